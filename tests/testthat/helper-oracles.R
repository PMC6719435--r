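# Independent literal transcription of the single-compartment PCASL
# quantification, kept deliberately separate from the package's
# calibration-factor code path. Times in ms as printed; T1 in seconds.
eq1_cbf_literal <- function(sc, sl, spd, t1_s, lambda = 0.9, pld_ms = 2000,
                            tau_ms = 1800, alpha = 0.85) {
  6000 * lambda * exp((pld_ms / 1000) / t1_s) * (sc - sl) / spd /
    (2 * alpha * t1_s * (1 - exp(-(tau_ms / 1000) / t1_s)))
}

t1_literal <- function(hct_fraction) 1 / (0.52 * hct_fraction + 0.38)

# Small phantom used across tests to keep runtimes low; still contains
# pure-GM, pure-WM, CSF and mixed voxels.
small_phantom <- function(...) {
  make_phantom(phantom_spec(dim = c(16, 16, 6), ...))
}

# Table of printed stratified model contrasts used as frozen references
# (means/SDs in mL/100 g/min, mean difference fixed->hct, effect size d).
published_contrasts <- function() {
  data.frame(
    stratum = c("all", "men", "women", "we_all", "we_men", "we_women",
                "sa_all", "sa_men", "sa_women", "ac_all", "ac_men",
                "ac_women", "no_diabetes", "diabetes"),
    mean_fixed = c(50.1, 50.0, 50.2, 51.8, 51.1, 53.2, 49.1, 49.4, 48.7,
                   47.6, 47.7, 47.6, 50.5, 49.0),
    sd_fixed = c(7.9, 8.3, 7.2, 8.3, 8.6, 7.6, 7.3, 8.1, 5.8, 6.7, 7.0,
                 6.6, 7.8, 8.3),
    mean_hct = c(48.8, 49.6, 47.5, 51.1, 51.1, 51.1, 47.3, 48.4, 45.7,
                 45.8, 47.4, 44.5, 49.4, 47.2),
    sd_hct = c(7.3, 7.6, 6.8, 7.5, 7.7, 7.0, 6.7, 7.3, 5.0, 6.3, 6.4,
               6.0, 7.2, 7.5),
    mean_diff = c(-1.3, -0.4, -2.7, -0.7, 0.0, -2.1, -1.8, -1.0, -3.0,
                  -1.8, -0.3, -3.1, -1.1, -1.8),
    d = c(0.17, 0.05, 0.38, 0.09, 0.00, 0.29, 0.26, 0.14, 0.56, 0.29,
          0.04, 0.48, 0.15, 0.23))
}
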