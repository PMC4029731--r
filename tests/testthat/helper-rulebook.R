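# the printed rule book: every code (with representative expansions for each
# X family) and the likelihood/category of its row
rulebook_codes <- list(
  list("315.39", "high", "bulbar"), list("438.10", "high", "bulbar"),
  list("438.11", "high", "bulbar"), list("784.3", "high", "bulbar"),
  list("784.40", "high", "bulbar"), list("784.41", "high", "bulbar"),
  list("784.49", "high", "bulbar"), list("784.51", "high", "bulbar"),
  list("784.5", "high", "bulbar"), list("787.2", "high", "bulbar"),
  list("438.82", "high", "bulbar"), list("527.7", "high", "bulbar"),
  list("527.8", "high", "bulbar"), list("784.1", "high", "bulbar"),
  list("728.2", "high", "limb"), list("728.87", "high", "limb"),
  list("719.7", "high", "limb"), list("781.2", "high", "limb"),
  list("781.3", "high", "limb"), list("729.82", "high", "limb"),
  list("728.85", "high", "limb"), list("781.0", "high", "limb"),
  list("359.0", "high", "limb"), list("359.1", "high", "limb"),
  list("359.21", "high", "limb"), list("719.4", "moderate", "limb"),
  list("729.5", "moderate", "limb"),
  list("728.0", "moderate", "limb"), list("728.11", "moderate", "limb"),
  list("728.9", "moderate", "limb"))
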