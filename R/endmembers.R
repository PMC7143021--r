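#' Default endmember amplitude configuration
#'
#' Baseline peak amplitudes (arbitrary intensity units) for each element
#' group in each of the four endmembers: pure acacia honey, rape honey, and
#' the two high-fructose corn syrups (HFCS F55 / F90).  The encoding follows
#' the qualitative spectral contrasts of these materials: mineral emissions
#' (Mg, Ca, K) are present in both honeys and absent from the syrups; Na is
#' markedly stronger in acacia than in rape honey and near-absent in HFCS;
#' C/H/O/N and the CN band appear in all four (both honey and HFCS are
#' largely fructose/glucose), with the carbon-rich F90 syrup carrying the
#' strongest C and CN emission so that the F90 mixtures are the easiest to
#' quantify.  Si and the four unidentified lines are sample-independent
#' background lines shared by all endmembers.
#'
#' Each line amplitude is `level * strength`, where the per-line emission
#' strength is drawn once per seed as `U(1 - jitter, 1 + jitter)` and shared
#' by all endmembers: it models the line's transition strength, a property
#' of the emission itself, while the group level models the emitting
#' species' abundance in the sample.  Levels of 0 stay exactly 0, and the
#' acacia/rape Na levels differ enough that acacia is always the stronger.
#'
#' @param jitter Half-width of the per-line multiplicative jitter (default
#'   0.1, i.e. amplitudes within +/-10\% of the group level).
#' @return A list with elements `levels` (matrix, element group x endmember)
#'   and `jitter`.
#' @export
endmember_config <- function(jitter = 0.1) {
  groups <- c("C", "CN", "N", "O", "H", "Mg", "Ca", "Na", "K",
              "Si", "Unknown")
  kinds <- c("acacia", "rape", "hfcs55", "hfcs90")
  levels <- matrix(
    #        acacia rape hfcs55 hfcs90
    c(        20.0, 19.0,  26.0,  34.0,   # C
              12.0, 11.0,  15.0,  20.0,   # CN
               8.0,  8.0,   8.5,  11.5,   # N
               7.0,  7.0,   7.5,  10.0,   # O
              15.0, 15.0,  16.0,  20.0,   # H
              18.0, 14.0,   0.0,   0.0,   # Mg
              22.0, 17.0,   0.0,   0.0,   # Ca
              20.0,  7.0,   0.5,   0.5,   # Na
              30.0, 26.0,   0.0,   0.0,   # K
               2.5,  2.5,   2.5,   2.5,   # Si (shared background)
               1.5,  1.5,   1.5,   1.5),  # Unknown (shared background)
    nrow = length(groups), byrow = TRUE,
    dimnames = list(groups, kinds))
  stopifnot(jitter >= 0, jitter < 1)
  list(levels = levels, jitter = jitter)
}

endmember_kinds <- function() c("acacia", "rape", "hfcs55", "hfcs90")

#' Generate an endmember amplitude profile
#'
#' Draws a reproducible per-line amplitude profile for one endmember: the
#' seed determines a per-line emission-strength factor shared by all four
#' endmembers, which multiplies the endmember's group abundance level.
#' Endmembers generated from one seed therefore agree exactly on lines
#' whose group levels coincide (in particular the Si and unidentified
#' background lines), and mixtures of two such endmembers vary each line
#' through a single linear abundance term.
#'
#' @param kind One of `"acacia"`, `"rape"`, `"hfcs55"`, `"hfcs90"`.
#' @param seed Integer seed; identical `(kind, seed)` calls return identical
#'   profiles.
#' @param config Amplitude configuration, see [endmember_config()].
#' @param lines Line library, see [libs_line_library()].
#' @return An object of class `endmember_profile`: list with `kind`,
#'   `amplitudes` (named non-negative vector, one entry per line) and
#'   `lines`.
#' @examples
#' p <- make_endmember_profile("hfcs90", seed = 1)
#' all(p$amplitudes[line_element() %in% c("Mg", "Ca", "K")] == 0)  # TRUE
#' @export
make_endmember_profile <- function(kind, seed = 1L,
                                   config = endmember_config(),
                                   lines = libs_line_library()) {
  kinds <- endmember_kinds()
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% kinds))
    stop_("unknown endmember kind '%s'; expected one of %s",
          as.character(kind)[1L], paste(kinds, collapse = ", "))
  grp <- line_element(lines)
  if (!all(grp %in% rownames(config$levels)))
    stop_("config is missing amplitude levels for group(s): %s",
          paste(setdiff(grp, rownames(config$levels)), collapse = ", "))
  jit <- config$jitter
  ## per-line emission strengths: one draw per seed, shared across kinds
  strength <- withr::with_seed(
    child_seed(seed, 0L), runif(nrow(lines), 1 - jit, 1 + jit))
  amp <- config$levels[grp, kind] * strength
  names(amp) <- line_labels(lines)
  structure(list(kind = kind, amplitudes = amp, lines = lines),
            class = "endmember_profile")
}

#' Linearly mix two endmember profiles
#'
#' Binary mixing at adulterant mass fraction `fraction`: each line amplitude
#' is `(1 - fraction) * pure + fraction * adulterant`.
#'
#' @param pure,adulterant `endmember_profile` objects on the same line
#'   library.
#' @param fraction Adulterant fraction in `[0, 1]`.
#' @return An `endmember_profile` whose `kind` records the mixture.
#' @export
mix_profiles <- function(pure, adulterant, fraction) {
  stopifnot(inherits(pure, "endmember_profile"),
            inherits(adulterant, "endmember_profile"))
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction > 1)
    stop_("fraction must be a single number in [0, 1], got %s",
          format(fraction))
  if (!isTRUE(all.equal(pure$lines$wavelength_nm,
                        adulterant$lines$wavelength_nm)))
    stop_("profiles must share the same line library")
  amp <- (1 - fraction) * pure$amplitudes + fraction * adulterant$amplitudes
  structure(list(kind = sprintf("%s+%s@%.4f", pure$kind, adulterant$kind,
                                fraction),
                 amplitudes = amp, lines = pure$lines),
            class = "endmember_profile")
}
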