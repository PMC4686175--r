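{
  "n_frames": 5,
  "tracks": [
    {
      "label": 1,
      "t_init": 1,
      "t_end": 1,
      "parent": 0
    },
    {
      "label": 2,
      "t_init": 2,
      "t_end": 4,
      "parent": 1
    },
    {
      "label": 3,
      "t_init": 1,
      "t_end": 4,
      "parent": 0
    },
    {
      "label": 4,
      "t_init": 0,
      "t_end": 1,
      "parent": 0
    },
    {
      "label": 5,
      "t_init": 2,
      "t_end": 2,
      "parent": 0
    },
    {
      "label": 6,
      "t_init": 3,
      "t_end": 3,
      "parent": 5
    },
    {
      "label": 7,
      "t_init": 2,
      "t_end": 2,
      "parent": 0
    },
    {
      "label": 8,
      "t_init": 3,
      "t_end": 4,
      "parent": 7
    },
    {
      "label": 9,
      "t_init": 0,
      "t_end": 2,
      "parent": 0
    }
  ],
  "markers": [
    {
      "label": 4,
      "frame": 0,
      "pixels": [
        [9, 29],
        [10, 29],
        [11, 29],
        [9, 30],
        [10, 30],
        [11, 30],
        [9, 31],
        [10, 31],
        [11, 31]
      ]
    },
    {
      "label": 9,
      "frame": 0,
      "pixels": [
        [9, 59],
        [10, 59],
        [11, 59],
        [9, 60],
        [10, 60],
        [11, 60],
        [9, 61],
        [10, 61],
        [11, 61]
      ]
    },
    {
      "label": 1,
      "frame": 1,
      "pixels": [
        [9, 9],
        [10, 9],
        [11, 9],
        [9, 10],
        [10, 10],
        [11, 10],
        [9, 11],
        [10, 11],
        [11, 11]
      ]
    },
    {
      "label": 3,
      "frame": 1,
      "pixels": [
        [9, 19],
        [10, 19],
        [11, 19],
        [9, 20],
        [10, 20],
        [11, 20],
        [9, 21],
        [10, 21],
        [11, 21]
      ]
    },
    {
      "label": 4,
      "frame": 1,
      "pixels": [
        [9, 29],
        [10, 29],
        [11, 29],
        [9, 30],
        [10, 30],
        [11, 30],
        [9, 31],
        [10, 31],
        [11, 31]
      ]
    },
    {
      "label": 9,
      "frame": 1,
      "pixels": [
        [9, 59],
        [10, 59],
        [11, 59],
        [9, 60],
        [10, 60],
        [11, 60],
        [9, 61],
        [10, 61],
        [11, 61]
      ]
    },
    {
      "label": 2,
      "frame": 2,
      "pixels": [
        [9, 9],
        [10, 9],
        [11, 9],
        [9, 10],
        [10, 10],
        [11, 10],
        [9, 11],
        [10, 11],
        [11, 11]
      ]
    },
    {
      "label": 3,
      "frame": 2,
      "pixels": [
        [9, 16],
        [10, 16],
        [11, 16],
        [9, 17],
        [10, 17],
        [11, 17],
        [9, 18],
        [10, 18],
        [11, 18],
        [9, 19],
        [10, 19],
        [11, 19],
        [9, 20],
        [10, 20],
        [11, 20],
        [9, 21],
        [10, 21],
        [11, 21],
        [9, 22],
        [10, 22],
        [11, 22],
        [9, 23],
        [10, 23],
        [11, 23],
        [9, 24],
        [10, 24],
        [11, 24]
      ]
    },
    {
      "label": 5,
      "frame": 2,
      "pixels": [
        [9, 29],
        [10, 29],
        [11, 29],
        [9, 30],
        [10, 30],
        [11, 30],
        [9, 31],
        [10, 31],
        [11, 31]
      ]
    },
    {
      "label": 7,
      "frame": 2,
      "pixels": [
        [9, 39],
        [10, 39],
        [11, 39],
        [9, 40],
        [10, 40],
        [11, 40],
        [9, 41],
        [10, 41],
        [11, 41]
      ]
    },
    {
      "label": 9,
      "frame": 2,
      "pixels": [
        [9, 59],
        [10, 59],
        [11, 59],
        [9, 60],
        [10, 60],
        [11, 60],
        [9, 61],
        [10, 61],
        [11, 61]
      ]
    },
    {
      "label": 2,
      "frame": 3,
      "pixels": [
        [9, 9],
        [10, 9],
        [11, 9],
        [9, 10],
        [10, 10],
        [11, 10],
        [9, 11],
        [10, 11],
        [11, 11]
      ]
    },
    {
      "label": 3,
      "frame": 3,
      "pixels": [
        [9, 16],
        [10, 16],
        [11, 16],
        [9, 17],
        [10, 17],
        [11, 17],
        [9, 18],
        [10, 18],
        [11, 18],
        [9, 19],
        [10, 19],
        [11, 19],
        [9, 20],
        [10, 20],
        [11, 20],
        [9, 21],
        [10, 21],
        [11, 21],
        [9, 22],
        [10, 22],
        [11, 22],
        [9, 23],
        [10, 23],
        [11, 23],
        [9, 24],
        [10, 24],
        [11, 24]
      ]
    },
    {
      "label": 6,
      "frame": 3,
      "pixels": [
        [9, 29],
        [10, 29],
        [11, 29],
        [9, 30],
        [10, 30],
        [11, 30],
        [9, 31],
        [10, 31],
        [11, 31]
      ]
    },
    {
      "label": 8,
      "frame": 3,
      "pixels": [
        [9, 37],
        [10, 37],
        [11, 37],
        [9, 38],
        [10, 38],
        [11, 38],
        [9, 39],
        [10, 39],
        [11, 39]
      ]
    },
    {
      "label": 2,
      "frame": 4,
      "pixels": [
        [9, 9],
        [10, 9],
        [11, 9],
        [9, 10],
        [10, 10],
        [11, 10],
        [9, 11],
        [10, 11],
        [11, 11],
        [9, 29],
        [10, 29],
        [11, 29],
        [9, 30],
        [10, 30],
        [11, 30],
        [9, 31],
        [10, 31],
        [11, 31]
      ]
    },
    {
      "label": 3,
      "frame": 4,
      "pixels": [
        [9, 16],
        [10, 16],
        [11, 16],
        [9, 17],
        [10, 17],
        [11, 17],
        [9, 18],
        [10, 18],
        [11, 18],
        [9, 19],
        [10, 19],
        [11, 19],
        [9, 20],
        [10, 20],
        [11, 20],
        [9, 21],
        [10, 21],
        [11, 21],
        [9, 22],
        [10, 22],
        [11, 22],
        [9, 23],
        [10, 23],
        [11, 23],
        [9, 24],
        [10, 24],
        [11, 24]
      ]
    },
    {
      "label": 8,
      "frame": 4,
      "pixels": [
        [9, 37],
        [10, 37],
        [11, 37],
        [9, 38],
        [10, 38],
        [11, 38],
        [9, 39],
        [10, 39],
        [11, 39],
        [9, 40],
        [10, 40],
        [11, 40],
        [9, 41],
        [10, 41],
        [11, 41],
        [9, 42],
        [10, 42],
        [11, 42],
        [9, 43],
        [10, 43],
        [11, 43]
      ]
    }
  ]
}
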