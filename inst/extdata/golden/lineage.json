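{
  "focal": [1, 2, 3, 4, 5, 6, 7, 8],
  "species": ["CM15", "SUR"],
  "steps": [
    {
      "frame": 2,
      "time_ns": 10,
      "members": [1, 2, 5, 6],
      "predecessor": [1, 2, 5, 6],
      "gained": [],
      "lost": [],
      "nucleated": false,
      "delta": {
        "CM15": 0,
        "SUR": 0
      }
    },
    {
      "frame": 3,
      "time_ns": 20,
      "members": [1, 2, 5, 6],
      "predecessor": [1, 2, 5, 6],
      "gained": [],
      "lost": [],
      "nucleated": false,
      "delta": {
        "CM15": 0,
        "SUR": 0
      }
    },
    {
      "frame": 4,
      "time_ns": 30,
      "members": [1, 2, 5, 6],
      "predecessor": [1, 2, 5, 6],
      "gained": [],
      "lost": [],
      "nucleated": false,
      "delta": {
        "CM15": 0,
        "SUR": 0
      }
    },
    {
      "frame": 5,
      "time_ns": 40,
      "members": [1, 2, 3, 4, 5, 6, 7, 8],
      "predecessor": [1, 2, 5, 6],
      "gained": [3, 4, 7, 8],
      "lost": [],
      "nucleated": false,
      "delta": {
        "CM15": 2,
        "SUR": 2
      }
    },
    {
      "frame": 6,
      "time_ns": 50,
      "members": [1, 2, 3, 4, 5, 6, 7, 8],
      "predecessor": [1, 2, 3, 4, 5, 6, 7, 8],
      "gained": [],
      "lost": [],
      "nucleated": false,
      "delta": {
        "CM15": 0,
        "SUR": 0
      }
    },
    {
      "frame": 7,
      "time_ns": 60,
      "members": [1, 2, 3, 4, 5, 6, 7, 8],
      "predecessor": [1, 2, 3, 4, 5, 6, 7, 8],
      "gained": [],
      "lost": [],
      "nucleated": false,
      "delta": {
        "CM15": 0,
        "SUR": 0
      }
    },
    {
      "frame": 8,
      "time_ns": 70,
      "members": [1, 2, 3, 4, 5, 6, 7, 8],
      "predecessor": [1, 2, 3, 4, 5, 6, 7, 8],
      "gained": [],
      "lost": [],
      "nucleated": false,
      "delta": {
        "CM15": 0,
        "SUR": 0
      }
    },
    {
      "frame": 9,
      "time_ns": 80,
      "members": [1, 2, 3, 4, 5, 6, 7, 8],
      "predecessor": [1, 2, 3, 4, 5, 6, 7, 8],
      "gained": [],
      "lost": [],
      "nucleated": false,
      "delta": {
        "CM15": 0,
        "SUR": 0
      }
    },
    {
      "frame": 10,
      "time_ns": 90,
      "members": [1, 2, 3, 4, 5, 6, 7, 8],
      "predecessor": [1, 2, 3, 4, 5, 6, 7, 8],
      "gained": [],
      "lost": [],
      "nucleated": false,
      "delta": {
        "CM15": 0,
        "SUR": 0
      }
    },
    {
      "frame": 11,
      "time_ns": 100,
      "members": [1, 2, 3, 4, 5, 6, 7, 8],
      "predecessor": [1, 2, 3, 4, 5, 6, 7, 8],
      "gained": [],
      "lost": [],
      "nucleated": false,
      "delta": {
        "CM15": 0,
        "SUR": 0
      }
    },
    {
      "frame": 12,
      "time_ns": 110,
      "members": [1, 2, 3, 4, 5, 6, 7, 8],
      "predecessor": [1, 2, 3, 4, 5, 6, 7, 8],
      "gained": [],
      "lost": [],
      "nucleated": false,
      "delta": {
        "CM15": 0,
        "SUR": 0
      }
    }
  ]
}
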