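{
  "comment": "Pooled correlation matrix and construct reliabilities of the motivating ASD parenting meta-analysis, construct order (parenting_stress, social_support, quality_of_life); 'groups' holds the east/west pooled matrices used for the sociocultural group comparison.",
  "constructs": ["parenting_stress", "social_support", "quality_of_life"],
  "r": [[1.0, -0.346, -0.470],
        [-0.346, 1.0, 0.474],
        [-0.470, 0.474, 1.0]],
  "reliability": {"parenting_stress": 0.860, "social_support": 0.837, "quality_of_life": 0.874},
  "cell_k": {"SS-PS": 23, "PS-QoL": 9, "SS-QoL": 12},
  "cell_n": {"SS-PS": 6051, "PS-QoL": 3242, "SS-QoL": 4127},
  "groups": {
    "east": [[1.0, -0.351, -0.438],
             [-0.351, 1.0, 0.493],
             [-0.438, 0.493, 1.0]],
    "west": [[1.0, -0.324, -0.518],
             [-0.324, 1.0, 0.442],
             [-0.518, 0.442, 1.0]]
  }
}
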