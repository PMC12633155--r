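grid_size: 100
mask:
  cells:
  - - 0
    - 0
  - - 99
    - 0
  - - 1
    - 1
  - - 98
    - 1
  - - 2
    - 2
  - - 97
    - 2
  - - 3
    - 3
  - - 96
    - 3
  - - 4
    - 4
  - - 95
    - 4
  - - 5
    - 5
  - - 94
    - 5
  - - 6
    - 6
  - - 93
    - 6
  - - 7
    - 7
  - - 92
    - 7
  - - 8
    - 8
  - - 91
    - 8
  - - 9
    - 9
  - - 90
    - 9
  - - 10
    - 10
  - - 89
    - 10
  - - 11
    - 11
  - - 88
    - 11
  - - 12
    - 12
  - - 87
    - 12
  - - 13
    - 13
  - - 86
    - 13
  - - 14
    - 14
  - - 85
    - 14
  - - 15
    - 15
  - - 84
    - 15
  - - 16
    - 16
  - - 83
    - 16
  - - 17
    - 17
  - - 82
    - 17
  - - 18
    - 18
  - - 81
    - 18
  - - 19
    - 19
  - - 80
    - 19
  - - 20
    - 20
  - - 79
    - 20
  - - 21
    - 21
  - - 78
    - 21
  - - 22
    - 22
  - - 77
    - 22
  - - 23
    - 23
  - - 76
    - 23
  - - 24
    - 24
  - - 75
    - 24
  - - 25
    - 25
  - - 74
    - 25
  - - 26
    - 26
  - - 73
    - 26
  - - 27
    - 27
  - - 72
    - 27
  - - 28
    - 28
  - - 71
    - 28
  - - 29
    - 29
  - - 70
    - 29
  - - 30
    - 30
  - - 69
    - 30
  - - 31
    - 31
  - - 68
    - 31
  - - 32
    - 32
  - - 67
    - 32
  - - 33
    - 33
  - - 66
    - 33
  - - 34
    - 34
  - - 65
    - 34
  - - 35
    - 35
  - - 64
    - 35
  - - 36
    - 36
  - - 63
    - 36
  - - 37
    - 37
  - - 62
    - 37
  - - 38
    - 38
  - - 61
    - 38
  - - 39
    - 39
  - - 60
    - 39
  - - 40
    - 40
  - - 59
    - 40
  - - 41
    - 41
  - - 58
    - 41
  - - 42
    - 42
  - - 57
    - 42
  - - 43
    - 43
  - - 56
    - 43
  - - 44
    - 44
  - - 55
    - 44
  - - 45
    - 45
  - - 54
    - 45
  - - 46
    - 46
  - - 53
    - 46
  - - 47
    - 47
  - - 52
    - 47
  - - 48
    - 48
  - - 51
    - 48
  - - 49
    - 49
  - - 50
    - 49
  - - 49
    - 50
  - - 50
    - 50
  - - 48
    - 51
  - - 51
    - 51
  - - 47
    - 52
  - - 52
    - 52
  - - 46
    - 53
  - - 53
    - 53
  - - 45
    - 54
  - - 54
    - 54
  - - 44
    - 55
  - - 55
    - 55
  - - 43
    - 56
  - - 56
    - 56
  - - 42
    - 57
  - - 57
    - 57
  - - 41
    - 58
  - - 58
    - 58
  - - 40
    - 59
  - - 59
    - 59
  - - 39
    - 60
  - - 60
    - 60
  - - 38
    - 61
  - - 61
    - 61
  - - 37
    - 62
  - - 62
    - 62
  - - 36
    - 63
  - - 63
    - 63
  - - 35
    - 64
  - - 64
    - 64
  - - 34
    - 65
  - - 65
    - 65
  - - 33
    - 66
  - - 66
    - 66
  - - 32
    - 67
  - - 67
    - 67
  - - 31
    - 68
  - - 68
    - 68
  - - 30
    - 69
  - - 69
    - 69
  - - 29
    - 70
  - - 70
    - 70
  - - 28
    - 71
  - - 71
    - 71
  - - 27
    - 72
  - - 72
    - 72
  - - 26
    - 73
  - - 73
    - 73
  - - 25
    - 74
  - - 74
    - 74
  - - 24
    - 75
  - - 75
    - 75
  - - 23
    - 76
  - - 76
    - 76
  - - 22
    - 77
  - - 77
    - 77
  - - 21
    - 78
  - - 78
    - 78
  - - 20
    - 79
  - - 79
    - 79
  - - 19
    - 80
  - - 80
    - 80
  - - 18
    - 81
  - - 81
    - 81
  - - 17
    - 82
  - - 82
    - 82
  - - 16
    - 83
  - - 83
    - 83
  - - 15
    - 84
  - - 84
    - 84
  - - 14
    - 85
  - - 85
    - 85
  - - 13
    - 86
  - - 86
    - 86
  - - 12
    - 87
  - - 87
    - 87
  - - 11
    - 88
  - - 88
    - 88
  - - 10
    - 89
  - - 89
    - 89
  - - 9
    - 90
  - - 90
    - 90
  - - 8
    - 91
  - - 91
    - 91
  - - 7
    - 92
  - - 92
    - 92
  - - 6
    - 93
  - - 93
    - 93
  - - 5
    - 94
  - - 94
    - 94
  - - 4
    - 95
  - - 95
    - 95
  - - 3
    - 96
  - - 96
    - 96
  - - 2
    - 97
  - - 97
    - 97
  - - 1
    - 98
  - - 98
    - 98
  - - 0
    - 99
  - - 99
    - 99
assignments:
  TGFB: 1.0
default_input: 0.0
duration: 500
snapshots:
- 0
- 100
- 300
- 500
fixed_dt: 0.1
name: case02_tgfb_x
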