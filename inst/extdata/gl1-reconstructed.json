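{
  "format": "sedem-study",
  "version": 1,
  "batches": [
    {
      "source_id": "Glenmarck",
      "batch_id": "GL-1",
      "scale": "pilot",
      "replicates": [
        {
          "density": {
            "sample_mass": 100,
            "poured_volume": 233.100233100233,
            "tapped_volume": 182.481751824818
          },
          "cohesion": {
            "hardness_values": [
              31.8,
              31.8,
              31.8
            ],
            "lubricated": true,
            "compressible": true
          },
          "repose": {
            "cone_height": 33.7428302328534,
            "base_radii": [
              40,
              40,
              40,
              40
            ]
          },
          "flow": {
            "seconds_per_100g": null,
            "non_flowing": true
          },
          "moisture": {
            "loss_on_drying_pct": 0.17,
            "hygroscopicity_pct": 0
          },
          "sieve": {
            "apertures": [
              355,
              212,
              100,
              50
            ],
            "retained_pct": [
              0,
              10.4052287581699,
              29.5947712418301,
              0
            ],
            "pan_pct": 60,
            "fines_direct_pct": 12.4
          },
          "psd": null
        },
        {
          "density": {
            "sample_mass": 100,
            "poured_volume": 244.498777506112,
            "tapped_volume": 187.265917602996
          },
          "cohesion": {
            "hardness_values": [
              36.6,
              36.6,
              36.6
            ],
            "lubricated": true,
            "compressible": true
          },
          "repose": {
            "cone_height": 38.1581022363105,
            "base_radii": [
              40,
              40,
              40,
              40
            ]
          },
          "flow": {
            "seconds_per_100g": null,
            "non_flowing": true
          },
          "moisture": {
            "loss_on_drying_pct": 0.220000000000001,
            "hygroscopicity_pct": 0.0199999999999996
          },
          "sieve": {
            "apertures": [
              355,
              212,
              100,
              50
            ],
            "retained_pct": [
              0,
              11.5935828877005,
              28.4064171122995,
              0
            ],
            "pan_pct": 60,
            "fines_direct_pct": 12.75
          },
          "psd": null
        },
        {
          "density": {
            "sample_mass": 100,
            "poured_volume": 240.384615384615,
            "tapped_volume": 185.873605947955
          },
          "cohesion": {
            "hardness_values": [
              42.6,
              42.6,
              42.6
            ],
            "lubricated": true,
            "compressible": true
          },
          "repose": {
            "cone_height": 34.8328001286477,
            "base_radii": [
              40,
              40,
              40,
              40
            ]
          },
          "flow": {
            "seconds_per_100g": null,
            "non_flowing": true
          },
          "moisture": {
            "loss_on_drying_pct": 0.24,
            "hygroscopicity_pct": 0.0199999999999996
          },
          "sieve": {
            "apertures": [
              355,
              212,
              100,
              50
            ],
            "retained_pct": [
              0,
              22.5817888799355,
              17.4182111200645,
              0
            ],
            "pan_pct": 60,
            "fines_direct_pct": 11.3
          },
          "psd": null
        }
      ]
    }
  ]
}
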