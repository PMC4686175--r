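{
  "n_frames": 5,
  "tracks": [
    {
      "label": 1,
      "t_init": 0,
      "t_end": 4,
      "parent": 0
    },
    {
      "label": 2,
      "t_init": 0,
      "t_end": 1,
      "parent": 0
    },
    {
      "label": 3,
      "t_init": 2,
      "t_end": 4,
      "parent": 2
    },
    {
      "label": 4,
      "t_init": 2,
      "t_end": 4,
      "parent": 2
    },
    {
      "label": 5,
      "t_init": 0,
      "t_end": 4,
      "parent": 0
    },
    {
      "label": 6,
      "t_init": 0,
      "t_end": 2,
      "parent": 0
    },
    {
      "label": 7,
      "t_init": 3,
      "t_end": 4,
      "parent": 0
    },
    {
      "label": 8,
      "t_init": 3,
      "t_end": 4,
      "parent": 6
    }
  ],
  "markers": [
    {
      "label": 1,
      "frame": 0,
      "pixels": [
        [10, 10]
      ]
    },
    {
      "label": 2,
      "frame": 0,
      "pixels": [
        [10, 20]
      ]
    },
    {
      "label": 5,
      "frame": 0,
      "pixels": [
        [10, 30]
      ]
    },
    {
      "label": 6,
      "frame": 0,
      "pixels": [
        [10, 40]
      ]
    },
    {
      "label": 1,
      "frame": 1,
      "pixels": [
        [10, 10]
      ]
    },
    {
      "label": 2,
      "frame": 1,
      "pixels": [
        [10, 20]
      ]
    },
    {
      "label": 5,
      "frame": 1,
      "pixels": [
        [10, 30]
      ]
    },
    {
      "label": 6,
      "frame": 1,
      "pixels": [
        [10, 40]
      ]
    },
    {
      "label": 1,
      "frame": 2,
      "pixels": [
        [10, 10]
      ]
    },
    {
      "label": 3,
      "frame": 2,
      "pixels": [
        [10, 18]
      ]
    },
    {
      "label": 4,
      "frame": 2,
      "pixels": [
        [10, 22]
      ]
    },
    {
      "label": 5,
      "frame": 2,
      "pixels": [
        [10, 30]
      ]
    },
    {
      "label": 6,
      "frame": 2,
      "pixels": [
        [10, 40]
      ]
    },
    {
      "label": 1,
      "frame": 3,
      "pixels": [
        [10, 10]
      ]
    },
    {
      "label": 3,
      "frame": 3,
      "pixels": [
        [10, 18]
      ]
    },
    {
      "label": 4,
      "frame": 3,
      "pixels": [
        [10, 22]
      ]
    },
    {
      "label": 5,
      "frame": 3,
      "pixels": [
        [10, 30]
      ]
    },
    {
      "label": 7,
      "frame": 3,
      "pixels": [
        [10, 38]
      ]
    },
    {
      "label": 8,
      "frame": 3,
      "pixels": [
        [10, 42]
      ]
    },
    {
      "label": 1,
      "frame": 4,
      "pixels": [
        [10, 10]
      ]
    },
    {
      "label": 3,
      "frame": 4,
      "pixels": [
        [10, 18]
      ]
    },
    {
      "label": 4,
      "frame": 4,
      "pixels": [
        [10, 22]
      ]
    },
    {
      "label": 5,
      "frame": 4,
      "pixels": [
        [10, 30]
      ]
    },
    {
      "label": 7,
      "frame": 4,
      "pixels": [
        [10, 38]
      ]
    },
    {
      "label": 8,
      "frame": 4,
      "pixels": [
        [10, 42]
      ]
    }
  ]
}
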