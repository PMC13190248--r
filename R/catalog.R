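## Bundled synthetic SBS-96 signature catalogue.
##
## COSMIC reference profiles are not redistributed here; instead the catalogue
## is generated deterministically with the qualitative shape of each process
## (flat clock-like SBS5, C>A-dominated smoking SBS4, C>T-dominated platinum
## SBS31, etc.). Every profile is synthetic and labelled as such; the pipeline
## treats the catalogue as an input and works unchanged with a real one.

## Deterministic per-signature profile: substitution-type weights spread over
## the 16 contexts with a fixed low-discrepancy jitter so profiles are neither
## flat nor random across builds.
.make_profile <- function(type_weights, peak_channels = character(0),
                          peak_mass = 0, jitter_phase = 1) {
  chans <- sbs96Channels()
  sub_of <- substr(chans, 3, 5)
  w <- type_weights[sub_of] / 16
  # deterministic jitter from an irrational rotation; keeps contexts uneven
  j <- 0.5 + 0.45 * sin(jitter_phase * 2.399963 * seq_along(chans))
  w <- w * j
  w <- w / sum(w)
  if (length(peak_channels)) {
    w <- w * (1 - peak_mass)
    w[match(peak_channels, chans)] <- w[match(peak_channels, chans)] +
      peak_mass / length(peak_channels)
  }
  stats::setNames(w / sum(w), chans)
}

#' Bundled synthetic signature catalogue
#'
#' Deterministic, fully synthetic SBS-96 profiles named after the mutational
#' processes they emulate: clock-like ageing (SBS5, SBS40), tobacco smoking
#' (SBS4), platinum chemotherapy (SBS31, SBS35), procarbazine (SBS25), a
#' blood/haematopoietic-stem-cell signature (SBS-A), an alcohol-associated
#' liver signature (SBS-B), a neuronal signature (SBS-E) and a
#' temozolomide-like signature (SBS-F). The profiles are mutually separable
#' (pairwise cosine similarity well below 0.9) so exposure refitting and
#' catalogue matching are well posed.
#'
#' @return A \linkS4class{SignatureCatalog} (SBS96, 10 signatures).
#' @export
bundledCatalog <- function() {
  tw <- function(ca, cg, ct, ta, tc, tg) {
    stats::setNames(c(ca, cg, ct, ta, tc, tg),
                    c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  }
  profs <- cbind(
    SBS5     = .make_profile(tw(.10, .08, .30, .08, .36, .08), jitter_phase = 1),
    SBS40    = .make_profile(tw(.12, .30, .06, .10, .10, .32),
                             peak_channels = c("T[C>G]T", "A[T>G]A"),
                             peak_mass = 0.12, jitter_phase = 2),
    SBS4     = .make_profile(tw(.75, .05, .08, .04, .05, .03),
                             peak_channels = c("C[C>A]A", "C[C>A]C", "T[C>A]A"),
                             peak_mass = 0.30, jitter_phase = 3),
    SBS31    = .make_profile(tw(.06, .04, .70, .04, .12, .04),
                             peak_channels = c("C[C>T]C", "C[C>T]T"),
                             peak_mass = 0.45, jitter_phase = 4),
    SBS35    = .make_profile(tw(.20, .45, .20, .05, .05, .05),
                             peak_channels = c("A[C>G]A", "T[C>G]G", "G[C>A]G"),
                             peak_mass = 0.40, jitter_phase = 5),
    SBS25    = .make_profile(tw(.06, .05, .08, .60, .11, .10),
                             peak_channels = c("C[T>A]T", "T[T>A]C"),
                             peak_mass = 0.30, jitter_phase = 6),
    `SBS-A`  = .make_profile(tw(.04, .03, .06, .05, .72, .10),
                             peak_channels = c("A[T>C]A", "A[T>C]T", "C[T>C]A"),
                             peak_mass = 0.35, jitter_phase = 7),
    `SBS-B`  = .make_profile(tw(.05, .03, .07, .35, .42, .08),
                             peak_channels = c("C[T>A]G", "C[T>C]G"),
                             peak_mass = 0.40, jitter_phase = 8),
    `SBS-E`  = .make_profile(tw(.08, .35, .30, .06, .11, .10),
                             peak_channels = c("G[C>G]A", "G[C>T]A"),
                             peak_mass = 0.35, jitter_phase = 9),
    `SBS-F`  = .make_profile(tw(.03, .02, .80, .04, .07, .04),
                             peak_channels = c("T[C>T]C", "T[C>T]T", "G[C>T]C"),
                             peak_mass = 0.50, jitter_phase = 10)
  )
  SignatureCatalog(profs, channelSet = "SBS96")
}
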