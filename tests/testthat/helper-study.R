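# The protocol-scale synthetic study (20 subjects, 3 compressions x 4
# angles, generator defaults, 20 dB SNR) is expensive; it is run once and
# shared by the acceptance checks that consume it.
study_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (is.null(study_cache$study)) {
    cfg <- study_config(n_dense = 10, n_nondense = 10, seed = 2026)
    study_cache$config <- cfg
    study_cache$study <- run_study(cfg)
  }
  list(study = study_cache$study, config = study_cache$config)
}
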