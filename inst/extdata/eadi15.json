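{
  "name": "eADI-15",
  "provenance": "Adaptation of eADI-17 for the 96-item FFQ1997, which lacks the seeds and legumes questions; the 15 remaining criteria retain the eADI-17 cut-offs unchanged (whether the original adaptation re-derived tertiles on FFQ1997 data is not documented).",
  "criteria": [
    { "food": "wholegrains", "direction": "anti", "unit": "servings/day", "lo": 2.5, "hi": 4.0, "zero_anchored": false },
    { "food": "vegetables", "direction": "anti", "unit": "servings/day", "lo": 2.2, "hi": 3.8, "zero_anchored": false },
    { "food": "coffee", "direction": "anti", "unit": "servings/day", "lo": 2.0, "hi": 3.0, "zero_anchored": false },
    { "food": "olive_canola_oil", "direction": "anti", "unit": "usage-count", "lo": 0, "hi": 1, "zero_anchored": true },
    { "food": "chicken", "direction": "anti", "unit": "servings/week", "lo": 0, "hi": 0.5, "zero_anchored": true },
    { "food": "eggs", "direction": "anti", "unit": "servings/week", "lo": 1.0, "hi": 2.0, "zero_anchored": false },
    { "food": "muesli", "direction": "anti", "unit": "servings/week", "lo": 0, "hi": 3.5, "zero_anchored": true },
    { "food": "nuts", "direction": "anti", "unit": "servings/week", "lo": 0, "hi": 1.0, "zero_anchored": true },
    { "food": "wine", "direction": "anti", "unit": "servings/week", "lo": 0.2, "hi": 1.5, "zero_anchored": false },
    { "food": "processed_meat", "direction": "pro", "unit": "servings/day", "lo": 0.8, "hi": 1.5, "zero_anchored": false },
    { "food": "other_processed_foods", "direction": "pro", "unit": "servings/day", "lo": 1.5, "hi": 2.5, "zero_anchored": false },
    { "food": "boiled_potatoes", "direction": "pro", "unit": "servings/day", "lo": 0.5, "hi": 0.7, "zero_anchored": false },
    { "food": "milk_3pct", "direction": "pro", "unit": "servings/day", "lo": 0, "hi": 0.9, "zero_anchored": true },
    { "food": "sugar_honey", "direction": "pro", "unit": "servings/day", "lo": 0, "hi": 0.9, "zero_anchored": true },
    { "food": "soft_drinks", "direction": "pro", "unit": "servings/day", "lo": 0, "hi": 0.2, "zero_anchored": true }
  ]
}
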