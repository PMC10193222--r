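{
  "schema_version": 1,
  "bank": "song",
  "comment": "20-song bank encoded as note counts only (one song = one level). Note counts are realistic lengths for simple one-line piano versions of well-known rhymes and compositions; no musical notation ships with the engine.",
  "songs": [
    {"song_id": "rock_a_bye_baby", "n_notes": 28},
    {"song_id": "wheels_on_the_bus", "n_notes": 33},
    {"song_id": "ode_to_joy", "n_notes": 62},
    {"song_id": "fur_elise_theme", "n_notes": 40},
    {"song_id": "twinkle_twinkle", "n_notes": 42},
    {"song_id": "row_your_boat", "n_notes": 27},
    {"song_id": "london_bridge", "n_notes": 25},
    {"song_id": "mary_had_a_little_lamb", "n_notes": 26},
    {"song_id": "happy_birthday", "n_notes": 25},
    {"song_id": "jingle_bells", "n_notes": 51},
    {"song_id": "old_macdonald", "n_notes": 34},
    {"song_id": "itsy_bitsy_spider", "n_notes": 35},
    {"song_id": "baa_baa_black_sheep", "n_notes": 31},
    {"song_id": "hot_cross_buns", "n_notes": 17},
    {"song_id": "frere_jacques", "n_notes": 32},
    {"song_id": "humpty_dumpty", "n_notes": 24},
    {"song_id": "hickory_dickory_dock", "n_notes": 26},
    {"song_id": "ring_a_ring_o_roses", "n_notes": 22},
    {"song_id": "yankee_doodle", "n_notes": 38},
    {"song_id": "brahms_lullaby", "n_notes": 36}
  ]
}
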