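######################
#....................#
#.###.###.##.###.###.#
#.###.###.##.###.###.#
#.###.###.##.###.###.#
#....................#
#.###.###.##.###.###.#
#.###.###.##.###.###.#
#.###.###.##.###.###.#
#....................#
#.###.###.##.###.###.#
#.###.###.##.###.###.#
#....................#
#.###.###.##.###.###.#
#.###.###.##.###.###.#
#.###.###.##.###.###.#
#....................#
#.###.###.##.###.###.#
#.###.###.##.###.###.#
#.###.###.##.###.###.#
#....................#
######################

# annotations: door <pair> <row> <col> | picture <id> <row> <col> <face> <texture>
#              reward <id> <row> <col> | bonus <row> <col> | start <row> <col> <heading>
door 1 4 6
door 1 4 10
door 2 4 13
door 2 4 17
door 3 8 6
door 3 8 10
door 4 8 13
door 4 8 17
door 5 15 6
door 5 15 10
door 6 15 13
door 6 15 17
door 7 19 10
door 7 19 13
picture 1 1 4 S 1
picture 2 1 15 S 2
picture 3 8 1 E 3
picture 4 15 1 E 4
picture 5 22 8 N 5
picture 6 22 15 N 6
picture 7 8 22 W 7
picture 8 15 22 W 8
picture 9 3 7 N 9
reward 1 6 6
reward 2 6 17
reward 3 17 17
reward 4 17 6
bonus 2 11
bonus 11 2
bonus 21 12
bonus 12 21
start 2 2 0
start 2 21 270
start 21 21 180
start 21 2 90
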