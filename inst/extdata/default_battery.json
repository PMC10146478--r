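{
  "min_items_required": 7,
  "items": [
    {"item_id": "belief_smoke_harm", "construct": "belief_consequences", "n_response_levels": 11, "desirable_high": true},
    {"item_id": "belief_alcohol_harm", "construct": "belief_consequences", "n_response_levels": 11, "desirable_high": true},
    {"item_id": "belief_drug_harm", "construct": "belief_consequences", "n_response_levels": 11, "desirable_high": true},
    {"item_id": "intent_avoid_alcohol", "construct": "intention_avoid", "n_response_levels": 11, "desirable_high": true},
    {"item_id": "intent_avoid_cigarette", "construct": "intention_avoid", "n_response_levels": 11, "desirable_high": true},
    {"item_id": "intent_avoid_marijuana", "construct": "intention_avoid", "n_response_levels": 11, "desirable_high": true},
    {"item_id": "norm_peer_drink", "construct": "normative_belief", "n_response_levels": 11, "desirable_high": false},
    {"item_id": "norm_peer_smoke", "construct": "normative_belief", "n_response_levels": 11, "desirable_high": false},
    {"item_id": "norm_peer_drunk", "construct": "normative_belief", "n_response_levels": 11, "desirable_high": false},
    {"item_id": "norm_accept_use", "construct": "normative_belief", "n_response_levels": 11, "desirable_high": false},
    {"item_id": "refuse_alcohol", "construct": "refusal_ease", "n_response_levels": 11, "desirable_high": true},
    {"item_id": "refuse_cigarette", "construct": "refusal_ease", "n_response_levels": 11, "desirable_high": true},
    {"item_id": "refuse_marijuana", "construct": "refusal_ease", "n_response_levels": 11, "desirable_high": true}
  ]
}
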