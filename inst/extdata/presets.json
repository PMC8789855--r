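{
  "channel": {
    "decyl": {
      "occupancy": [
        0.1,
        0.21,
        0.69
      ],
      "a": 0.08,
      "d": 0.03,
      "level_mean": [
        0.0,
        1.4,
        3.5
      ],
      "level_sd": 0.525
    },
    "octyl": {
      "occupancy": [
        0.14,
        0.45,
        0.41
      ],
      "a": 0.08,
      "d": 0.03,
      "level_mean": [
        0.0,
        1.4,
        3.5
      ],
      "level_sd": 0.525
    },
    "hexyl": {
      "occupancy": [
        0.06,
        0.48,
        0.46
      ],
      "a": 0.08,
      "d": 0.03,
      "level_mean": [
        0.0,
        1.4,
        3.5
      ],
      "level_sd": 0.525
    }
  },
  "pore": {
    "wildtype": {
      "collar_z": 0,
      "r_closed": 2.1,
      "r_open": 5.2,
      "ou_tau": 10,
      "ou_sigma": 0.3,
      "n_tails": 1,
      "engage_rate_in": 0.02,
      "engage_rate_out": 0.02,
      "open_threshold": 3,
      "water_count": 30,
      "barrier_B0": 25,
      "barrier_dB": 6
    }
  },
  "flux": {
    "active": {
      "F0": 5000,
      "F_inf": 1500,
      "k_decay": 0.1,
      "t_val": 35
    },
    "blocked": {
      "F0": 5000,
      "F_inf": 4800,
      "k_decay": 0.02,
      "t_val": 35
    }
  }
}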