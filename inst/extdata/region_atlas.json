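{
  "comment": "Artery region calibration. Each region is a sphere in landmark space: centre = mean of named anchor points plus offsets (in units of the outer inter-ocular distance) along landmark-derived directions, then pulled depth_pull towards the face centroid (facial arteries run subcutaneously, a few mm below the landmark surface); radius in the same units. Left side only; the right side is the mirror image across the midsagittal plane.",
  "version": 2,
  "depth_pull": 0.10,
  "regions": [
    {"artery": "Fa",  "anchors": ["mid_jaw_left", "mouth_corner_left"], "offsets": [], "radius": 0.30},
    {"artery": "IL",  "anchors": ["mouth_corner_left", "lip_bottom_mid"], "offsets": [{"dir": "down", "amount": 0.06}], "radius": 0.16},
    {"artery": "SL",  "anchors": ["mouth_corner_left", "lip_top_mid"], "offsets": [{"dir": "up", "amount": 0.04}], "radius": 0.16},
    {"artery": "Ang", "anchors": ["nose_wing_left", "eye_inner_left"], "offsets": [], "radius": 0.17},
    {"artery": "LN",  "anchors": ["nose_wing_left"], "offsets": [{"dir": "lat", "amount": 0.06}], "radius": 0.15},
    {"artery": "DN",  "anchors": ["bridge_mid"], "offsets": [{"dir": "lat", "amount": 0.07}], "radius": 0.14},
    {"artery": "STr", "anchors": ["brow_inner_left"], "offsets": [{"dir": "up", "amount": 0.05}], "radius": 0.16},
    {"artery": "SO",  "anchors": ["brow_mid_left"], "offsets": [{"dir": "up", "amount": 0.06}], "radius": 0.16},
    {"artery": "ST",  "anchors": ["eye_outer_left"], "offsets": [{"dir": "lat", "amount": 0.18}, {"dir": "up", "amount": 0.08}], "radius": 0.28}
  ]
}
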