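{
  "constructs": [
    {
      "left": "overweight",
      "right": "correct weight",
      "predefined": true
    },
    {
      "left": "uncontrolled eating",
      "right": "control of eating",
      "predefined": true
    },
    {
      "left": "enjoys eating",
      "right": "indifferent to eating",
      "predefined": true
    },
    {
      "left": "active",
      "right": "sedentary",
      "predefined": true
    },
    {
      "left": "healthy",
      "right": "unhealthy",
      "predefined": true
    },
    {
      "left": "confident",
      "right": "insecure",
      "predefined": true
    },
    {
      "left": "weak willpower",
      "right": "strong willpower",
      "predefined": false
    },
    {
      "left": "eats unhealthily",
      "right": "healthy eating",
      "predefined": false
    },
    {
      "left": "sad",
      "right": "cheerful",
      "predefined": false
    },
    {
      "left": "lazy",
      "right": "disciplined",
      "predefined": false
    },
    {
      "left": "stressed",
      "right": "calm",
      "predefined": false
    },
    {
      "left": "solitary",
      "right": "sociable",
      "predefined": false
    }
  ],
  "elements": [
    {
      "label": "Self-Now",
      "role": "self_now"
    },
    {
      "label": "Self-in-a-year",
      "role": "self_year"
    },
    {
      "label": "father",
      "role": "other"
    },
    {
      "label": "mother",
      "role": "other"
    },
    {
      "label": "partner / significant other",
      "role": "other"
    },
    {
      "label": "overweight person",
      "role": "other"
    },
    {
      "label": "not-overweight person",
      "role": "other"
    },
    {
      "label": "person with healthy habits",
      "role": "other"
    },
    {
      "label": "person without healthy habits",
      "role": "other"
    },
    {
      "label": "persona non grata",
      "role": "other"
    },
    {
      "label": "Ideal-Self",
      "role": "ideal_self"
    }
  ],
  "ratings": [
    [1, 4, 2, 5, 3, 1, 6, 6, 2, 3, 7],
    [3, 4, 3, 5, 4, 2, 5, 6, 2, 2, 7],
    [2, 2, 2, 3, 2, 1, 4, 5, 2, 6, 2],
    [6, 5, 5, 3, 4, 6, 2, 2, 6, 5, 1],
    [4, 4, 3, 4, 4, 5, 3, 2, 5, 6, 1],
    [5, 4, 3, 3, 4, 5, 3, 3, 5, 6, 2],
    [2, 3, 4, 5, 3, 2, 5, 6, 2, 3, 6],
    [2, 3, 3, 5, 3, 1, 5, 6, 2, 2, 7],
    [5, 5, 4, 5, 5, 3, 5, 5, 4, 2, 6],
    [3, 3, 4, 5, 4, 3, 5, 6, 2, 3, 6],
    [3, 3, 2, 4, 3, 3, 5, 5, 3, 2, 6],
    [5, 5, 4, 5, 6, 4, 5, 5, 4, 2, 6]
  ],
  "implications": [
    [0, 0, 0, -3, -3, -2, 0, 0, 0, 0, 0, 0],
    [0, 0, 2, 0, -2, 0, 0, 2, 0, 0, 0, 0],
    [0, 3, 0, 0, -2, 0, 2, 3, 0, 0, 0, 0],
    [2, 0, 0, 0, -2, -1, 0, 0, 0, 0, 0, 0],
    [2, 0, 2, 0, 0, 0, 0, 0, 1, 0, 0, 0],
    [0, 0, 0, 0, 0, 0, 0, 0, 2, 0, 0, 2],
    [0, 3, 2, 0, 0, 0, 0, 0, 0, 2, 0, 0],
    [2, 0, 3, 0, -3, 0, 0, 0, 0, 0, 0, 0],
    [0, 0, 0, 0, 0, 2, 0, 0, 0, 0, 0, 0],
    [0, 2, 0, -2, 0, 0, 0, 0, 0, 0, 0, 0],
    [0, 0, 0, 0, -1, 0, 0, 0, 2, 0, 0, 0],
    [0, 0, 0, 0, 0, 0, 0, 0, -2, 0, 0, 0]
  ],
  "meta": {
    "synthetic_completion": true,
    "note": "Worked healthy-habits case; only construct 1 ratings/implications and construct 2 self/ideal are anchored; all other cells are fixed synthetic completions."
  }
}
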