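{
  "schema_version": 1,
  "bank": "stimulus",
  "comment": "Abstract face-stimulus ids with valence tags; no image files ship with the engine.",
  "positive": [
    "face_pos_01", "face_pos_02", "face_pos_03", "face_pos_04",
    "face_pos_05", "face_pos_06", "face_pos_07", "face_pos_08",
    "face_pos_09", "face_pos_10", "face_pos_11", "face_pos_12"
  ],
  "negative": [
    "face_neg_01", "face_neg_02", "face_neg_03", "face_neg_04",
    "face_neg_05", "face_neg_06", "face_neg_07", "face_neg_08",
    "face_neg_09", "face_neg_10", "face_neg_11", "face_neg_12",
    "face_neg_13", "face_neg_14", "face_neg_15", "face_neg_16",
    "face_neg_17", "face_neg_18", "face_neg_19", "face_neg_20",
    "face_neg_21", "face_neg_22", "face_neg_23", "face_neg_24"
  ]
}
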