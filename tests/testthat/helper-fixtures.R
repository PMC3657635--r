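# Shared fixtures, memoized so the expensive synthetic experiment is built
# once per test session. Problem sizes: 1 session x 20 trials (20-track
# candidate pool), renderer 40 x 30 @ 20 fps, 40-voxel ROIs, TR 3 s, 2-TR lag.

.fx <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

fx_config <- function(snr, rois, sources, seed = 202L) {
  experiment_config(
    n_sessions = 1, trials_per_session = 20, rois = rois, snr = snr,
    sources = sources, width = 40, height = 30, weight_source = "same",
    seed = seed
  )
}

# behavioral side (tracks, scenes, 73 variables, track library) -- shared by
# every synthetic decoding fixture
fx_behavior <- function() {
  memo("behavior", simulate_behavior(fx_config(1, c(V1 = 40), "motion")))
}

fx_stage <- function(key, snr, rois, sources) {
  memo(key, {
    cfg <- fx_config(snr, rois, sources)
    behavior <- fx_behavior()
    aligned <- synthesize_signals(behavior, cfg)
    decoded <- decode_experiment(aligned, cfg)
    ranked <- rank_experiment(decoded$predictions, behavior, cfg)
    list(
      config = cfg, decoded = decoded, ranked = ranked,
      result = evaluate_experiment(behavior, decoded, ranked, cfg)
    )
  })
}

# white-matter control: zero tuning, all six information sources
fx_wm <- function() {
  fx_stage(
    "wm", 1, c(WM = 40),
    c("quadrant", "visibility", "motion", "reward", "scene_rms", "scene_temp")
  )
}

# tuned visual + motor ROIs at a given encoding snr; V1 is sized so that its
# tuned voxels can span its encoded variable set (single-variable readout is
# otherwise crosstalk-limited no matter how high the snr)
fx_tuned <- function(snr) {
  fx_stage(paste0("tuned_", snr), snr, c(V1 = 120, M1 = 40), c("scene_rms", "motion"))
}

# small constructed track library of smooth, independent random variable
# traces for two sources -- used by ranking/similarity tests
toy_library <- function(n_tracks = 24, n_tr = 20, seed = 7,
                        sources = c(motion = "motion", visibility = "vis1")) {
  withr::with_seed(seed, {
    sets <- lapply(seq_len(n_tracks), function(i) {
      dplyr::bind_rows(lapply(names(sources), function(src) {
        tibble::tibble(
          source = src, variable = sources[[src]], tr = seq_len(n_tr),
          value = as.numeric(stats::filter(rnorm(n_tr), rep(1 / 3, 3),
            circular = TRUE
          ))
        )
      }))
    })
    names(sets) <- as.character(seq_len(n_tracks))
    track_library(sets)
  })
}

# noisy predictions of one track's actual trace for the named source
toy_predictions <- function(library, track, source, noise_sd = 0.3, seed = 1) {
  lv <- library[library$source == source & library$track == as.character(track), ]
  withr::with_seed(seed, {
    tibble::tibble(
      variable = lv$variable, tr = lv$tr,
      predicted = lv$value + rnorm(nrow(lv), 0, noise_sd)
    )
  })
}

# a 22 x 22 single-corridor maze whose door pair 1 sits between the viewer
# and an end-wall picture: used for renderer occlusion tests
corridor_maze <- function() {
  g <- matrix("#", 22, 22)
  g[2, 2:21] <- "."
  lines <- apply(g, 1, paste, collapse = "")
  ann <- c(
    "door 1 2 10", "door 1 2 11",
    "door 2 2 4", "door 2 2 5",
    "door 3 2 6", "door 3 2 7",
    "door 4 2 8", "door 4 2 9",
    "door 5 2 16", "door 5 2 17",
    "door 6 2 18", "door 6 2 19",
    "door 7 2 14", "door 7 2 15",
    "picture 1 2 22 W 1",
    sprintf("picture %d 1 %d S %d", 2:9, 4:11, 2:9),
    "reward 1 2 3", "reward 2 2 12", "reward 3 2 13", "reward 4 2 20",
    "bonus 2 2", "bonus 2 21", "bonus 2 6", "bonus 2 18",
    "start 2 2 0"
  )
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(c(lines, ann), f)
  load_maze(f)
}

# independent brute-force BFS distance oracle (plain queue over tiles)
oracle_bfs_dist <- function(open, from, to) {
  nr <- nrow(open)
  dist <- matrix(NA_integer_, nr, ncol(open))
  dist[from[1], from[2]] <- 0L
  q <- list(from)
  while (length(q)) {
    cur <- q[[1]]
    q <- q[-1]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r <- cur[1] + d[1]
      c <- cur[2] + d[2]
      if (r < 1 || r > nr || c < 1 || c > ncol(open)) next
      if (!open[r, c] || !is.na(dist[r, c])) next
      dist[r, c] <- dist[cur[1], cur[2]] + 1L
      q[[length(q) + 1]] <- c(r, c)
    }
  }
  dist[to[1], to[2]]
}

# build a scene object directly from matrices (bypasses the renderer)
make_scene <- function(luminance, picture_mask = NULL) {
  structure(
    list(
      luminance = luminance,
      picture_mask = picture_mask %||%
        matrix(0L, nrow(luminance), ncol(luminance))
    ),
    class = "scene"
  )
}
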