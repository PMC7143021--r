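## small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

warn_ <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == floor(x)

## all user-facing seeds are folded below 2^31 so they are valid R integers
fold_seed <- function(seed) as.integer(abs(seed) %% 2147483587)

## deterministic child-seed derivation: master seed + a documented counter,
## so adding a consumer does not shift other branches' randomness
child_seed <- function(seed, counter) fold_seed(fold_seed(seed) + counter)

## columns whose variation is real rather than floating-point residue:
## a column is treated as constant when its SD is negligible relative to
## its magnitude (noiseless simulations leave ~1e-16 mixing round-off on
## lines shared by both endmembers, which autoscaling must never amplify)
nonconstant_cols <- function(X) {
  sds <- apply(X, 2L, sd)
  ref <- pmax(apply(abs(X), 2L, max), 1)
  sds > 1e-10 * ref
}
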