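# Bundled default lexicon for Gleason-score extraction.
#
# This is a reconstruction of an expert-curated term list: anchors that mark
# a Gleason-score mention, and specimen cues that classify a mention as
# prostate surgery vs prostate needle biopsy. Cues carry a tier: tier 1 terms
# are highly specific and take precedence over tier 2 terms whenever both
# appear in a search window. Matching is case-insensitive and whole-token.
# Users may supply their own file with the same schema via load_lexicon().
version: "1.0"
windows:
  parse_after: 60      # characters scanned after an anchor for components
  parse_before: 30     # characters scanned before an anchor (fallback)
  classify_radii: [150, 500]  # widening half-window radii; whole note last
terms:
  # --- Gleason mention anchors -------------------------------------------
  - {surface: "Gleason score", category: gleason_anchor, tier: 1}
  - {surface: "Gleason's score", category: gleason_anchor, tier: 1}
  - {surface: "Gleason grade", category: gleason_anchor, tier: 1}
  - {surface: "Gleason", category: gleason_anchor, tier: 1}
  - {surface: "GS", category: gleason_anchor, tier: 2}
  # --- Prostate surgery cues ---------------------------------------------
  - {surface: "radical prostatectomy", category: surgery_cue, tier: 1}
  - {surface: "retropubic radical prostatectomy", category: surgery_cue, tier: 1}
  - {surface: "prostatectomy", category: surgery_cue, tier: 1}
  - {surface: "RRP", category: surgery_cue, tier: 1}
  - {surface: "RALP", category: surgery_cue, tier: 1}
  - {surface: "prostate surgery", category: surgery_cue, tier: 2}
  - {surface: "pathologic stage", category: surgery_cue, tier: 2}
  - {surface: "surgical margins", category: surgery_cue, tier: 2}
  # --- Prostate biopsy cues ----------------------------------------------
  - {surface: "prostate needle biopsy", category: biopsy_cue, tier: 1}
  - {surface: "needle biopsy", category: biopsy_cue, tier: 1}
  - {surface: "core biopsy", category: biopsy_cue, tier: 1}
  - {surface: "PNBx", category: biopsy_cue, tier: 1}
  - {surface: "TRUS biopsy", category: biopsy_cue, tier: 1}
  - {surface: "prostate biopsy", category: biopsy_cue, tier: 1}
  - {surface: "Bx", category: biopsy_cue, tier: 1}
  - {surface: "biopsy", category: biopsy_cue, tier: 2}
  - {surface: "cores", category: biopsy_cue, tier: 2}
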