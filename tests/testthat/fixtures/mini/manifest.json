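{
  "seeds": {
    "specimens": 102,
    "trials": [77796, 77797]
  },
  "counts": {
    "trials": 2,
    "frames_generated": 30,
    "frames_trackable": 30,
    "frames_analyzed": 30,
    "report_rows": 36,
    "frames_pooled": 30
  },
  "files": ["config.json", "geometry.json", "trials/mini_hop/truth_femur.csv", "trials/mini_hop/model_femur.csv", "trials/mini_hop/truth_tibia.csv", "trials/mini_hop/model_tibia.csv", "trials/mini_hop/beads.csv", "trials/mini_hop/trial.json", "trials/mini_drop/truth_femur.csv", "trials/mini_drop/model_femur.csv", "trials/mini_drop/truth_tibia.csv", "trials/mini_drop/model_tibia.csv", "trials/mini_drop/beads.csv", "trials/mini_drop/trial.json", "trials/mini_hop/marker_femur.csv", "trials/mini_hop/marker_tibia.csv", "trials/mini_drop/marker_femur.csv", "trials/mini_drop/marker_tibia.csv", "trials/mini_hop/kinematics_marker.csv", "trials/mini_hop/kinematics_marker_norm.csv", "trials/mini_hop/kinematics_model.csv", "trials/mini_hop/kinematics_model_norm.csv", "trials/mini_drop/kinematics_marker.csv", "trials/mini_drop/kinematics_marker_norm.csv", "trials/mini_drop/kinematics_model.csv", "trials/mini_drop/kinematics_model_norm.csv", "report.csv", "report.json"],
  "config_hash": "b0198b6858e897391931200ab2edc02e",
  "package_version": "0.1.0",
  "stages": ["simulate", "track-markers", "kinematics", "agreement"]
}
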