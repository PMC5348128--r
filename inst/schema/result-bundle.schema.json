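{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "KymoQuant result bundle",
  "type": "object",
  "required": ["meta", "tracking", "diffusion", "clusters", "footprints",
               "rotationModel"],
  "properties": {
    "meta": {
      "type": "object",
      "required": ["package", "version", "seed", "linePeriod_s",
                   "pixelSize_nm"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"},
        "seed": {"type": "number"},
        "nTetramers": {"type": "number"},
        "linePeriod_s": {"type": "number"},
        "pixelSize_nm": {"type": "number"}
      }
    },
    "tracking": {
      "type": "object",
      "required": ["nTrajectories", "nDiffusive", "nStatic"],
      "properties": {
        "nTrajectories": {"type": "number"},
        "nDiffusive": {"type": "number"},
        "nStatic": {"type": "number"},
        "meanDyesPerTrajectory": {"type": ["number", "null"]}
      }
    },
    "diffusion": {
      "type": "object",
      "required": ["D_um2_s", "nTrajectories"],
      "properties": {
        "D_um2_s": {"type": ["number", "null"]},
        "D_sd": {"type": ["number", "null"]},
        "nTrajectories": {"type": "number"}
      }
    },
    "clusters": {
      "type": "object",
      "required": ["n", "meanTetramers"],
      "properties": {
        "n": {"type": "number"},
        "meanTetramers": {"type": ["number", "null"]}
      }
    },
    "footprints": {
      "type": "object",
      "required": ["compaction_nm", "flowBox_nm", "planted_nm"],
      "properties": {
        "compaction_nm": {"type": "number"},
        "compactionValid": {"type": "boolean"},
        "flowBox_nm": {"type": "number"},
        "planted_nm": {"type": "number"}
      }
    },
    "rotationModel": {
      "type": "object",
      "required": ["D_rotation_um2_s", "D_translation_um2_s", "barrierForm"],
      "properties": {
        "D_rotation_um2_s": {"type": "number"},
        "D_translation_um2_s": {"type": "number"},
        "ratio": {"type": "number"},
        "barrierForm": {"type": "string"}
      }
    }
  }
}
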