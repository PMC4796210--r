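{
  "required": ["subpockets", "pocket_volume", "summary_flags", "thresholds"],
  "subpocket_columns": ["x", "y", "z", "hotspot_energy",
                        "nearest_polar_hotspot_distance",
                        "unhappy_water_count", "druggable"]
}
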