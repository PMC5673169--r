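#' @keywords internal
"_PACKAGE"

# cells per cm^3 of tumor tissue: a 1 cm^3 tumor is taken to contain 1e9 cells
CELLS_PER_CM3 <- 1e9

# tumor tissue density used to convert necropsy weight (g) to volume (cm^3)
TUMOR_DENSITY_G_PER_CM3 <- 1.0

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a reproducible per-unit seed from a master seed and a unit id so
# cohort resizing does not reshuffle the streams of existing units.
# Kept strictly below 2^31.
derive_seed <- function(master_seed, id) {
  h <- sum(utf8ToInt(as.character(id)) * seq_along(utf8ToInt(as.character(id))))
  as.integer((as.numeric(master_seed) * 7919 + h) %% 2147483629)
}
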