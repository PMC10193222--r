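{
  "schema_version": 1,
  "bank": "wsap",
  "comment": "Replacement 42-item bank. Items 1-32 are ambiguous sentences (correct answer: yes for positive probes); items 33-42 are decoys: unambiguous negative-toned sentences whose negative word is genuinely related (correct answer: yes for negative probes).",
  "items": [
    {"sentence": "My mom called me to tell me the news", "probe_word": "exciting", "probe_valence": "positive", "is_decoy": false},
    {"sentence": "The boss wants to see me today", "probe_word": "trouble", "probe_valence": "negative", "is_decoy": false},
    {"sentence": "People looked at me as I walked in", "probe_word": "admired", "probe_valence": "positive", "is_decoy": false},
    {"sentence": "My friend sent me a long message", "probe_word": "caring", "probe_valence": "positive", "is_decoy": false},
    {"sentence": "The doctor asked me to come back", "probe_word": "serious", "probe_valence": "negative", "is_decoy": false},
    {"sentence": "Everyone went quiet when I spoke", "probe_word": "boring", "probe_valence": "negative", "is_decoy": false},
    {"sentence": "My neighbor left a note on my door", "probe_word": "friendly", "probe_valence": "positive", "is_decoy": false},
    {"sentence": "The teacher read my essay to the class", "probe_word": "impressed", "probe_valence": "positive", "is_decoy": false},
    {"sentence": "I got an email about my job today", "probe_word": "offer", "probe_valence": "positive", "is_decoy": false},
    {"sentence": "My sister laughed when she saw my gift", "probe_word": "delighted", "probe_valence": "positive", "is_decoy": false},
    {"sentence": "The crowd turned to look at me", "probe_word": "curious", "probe_valence": "positive", "is_decoy": false},
    {"sentence": "My landlord wants to talk about the flat", "probe_word": "eviction", "probe_valence": "negative", "is_decoy": false},
    {"sentence": "The results of my test came in", "probe_word": "passed", "probe_valence": "positive", "is_decoy": false},
    {"sentence": "My old friend is in town this week", "probe_word": "reunion", "probe_valence": "positive", "is_decoy": false},
    {"sentence": "The group chat went silent after my joke", "probe_word": "awkward", "probe_valence": "negative", "is_decoy": false},
    {"sentence": "My cousin is planning a surprise for me", "probe_word": "thoughtful", "probe_valence": "positive", "is_decoy": false},
    {"sentence": "The coach called my name at practice", "probe_word": "chosen", "probe_valence": "positive", "is_decoy": false},
    {"sentence": "People were talking about me at lunch", "probe_word": "gossip", "probe_valence": "negative", "is_decoy": false},
    {"sentence": "The letter from the bank arrived today", "probe_word": "overdrawn", "probe_valence": "negative", "is_decoy": false},
    {"sentence": "My date ended earlier than planned", "probe_word": "rejected", "probe_valence": "negative", "is_decoy": false},
    {"sentence": "The meeting ran long because of my idea", "probe_word": "inspired", "probe_valence": "positive", "is_decoy": false},
    {"sentence": "My photo was shared around the office", "probe_word": "mocked", "probe_valence": "negative", "is_decoy": false},
    {"sentence": "The new manager asked about my work", "probe_word": "interested", "probe_valence": "positive", "is_decoy": false},
    {"sentence": "My son brought home a note from school", "probe_word": "praise", "probe_valence": "positive", "is_decoy": false},
    {"sentence": "The party got loud after I arrived", "probe_word": "welcome", "probe_valence": "positive", "is_decoy": false},
    {"sentence": "My review at work is set for Friday", "probe_word": "raise", "probe_valence": "positive", "is_decoy": false},
    {"sentence": "The phone rang twice then stopped", "probe_word": "ignored", "probe_valence": "negative", "is_decoy": false},
    {"sentence": "My aunt wants to visit next month", "probe_word": "pleasant", "probe_valence": "positive", "is_decoy": false},
    {"sentence": "The dog barked when I came home", "probe_word": "excited", "probe_valence": "positive", "is_decoy": false},
    {"sentence": "My essay got more comments than usual", "probe_word": "helpful", "probe_valence": "positive", "is_decoy": false},
    {"sentence": "The waiter smiled as I paid the bill", "probe_word": "generous", "probe_valence": "positive", "is_decoy": false},
    {"sentence": "My team went out without telling me", "probe_word": "excluded", "probe_valence": "negative", "is_decoy": false},
    {"sentence": "I failed my exam for the third time", "probe_word": "hopeless", "probe_valence": "negative", "is_decoy": true},
    {"sentence": "My wallet was stolen on the train", "probe_word": "upset", "probe_valence": "negative", "is_decoy": true},
    {"sentence": "The storm ruined our whole trip", "probe_word": "awful", "probe_valence": "negative", "is_decoy": true},
    {"sentence": "I missed my flight and lost the fare", "probe_word": "careless", "probe_valence": "negative", "is_decoy": true},
    {"sentence": "My car broke down far from home", "probe_word": "stranded", "probe_valence": "negative", "is_decoy": true},
    {"sentence": "I lost the final game for my team", "probe_word": "proud", "probe_valence": "positive", "is_decoy": true},
    {"sentence": "My boss shouted at me in the hall", "probe_word": "valued", "probe_valence": "positive", "is_decoy": true},
    {"sentence": "I forgot my lines during the play", "probe_word": "confident", "probe_valence": "positive", "is_decoy": true},
    {"sentence": "My rent went up and my pay did not", "probe_word": "lucky", "probe_valence": "positive", "is_decoy": true},
    {"sentence": "I spilled coffee on my only suit", "probe_word": "stylish", "probe_valence": "positive", "is_decoy": true}
  ]
}
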