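#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"

# Multi-select cells use "|" between option labels; labels are opaque,
# case-sensitive tokens stripped of surrounding whitespace only.
split_opts <- function(x) {
  if (length(x) != 1L) stop("split_opts() expects a single cell", call. = FALSE)
  if (is.na(x) || !nzchar(x)) return(character())
  trimws(strsplit(x, "|", fixed = TRUE)[[1]])
}

join_opts <- function(x) paste(x, collapse = "|")

# Canonical form of an option set: sorted, "|"-joined. Two cells denote the
# same set iff their canonical forms are equal.
canonical_set <- function(x) join_opts(sort(unique(split_opts(x))))

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for reported percentages so that
#' e.g. 78/264 prints as 29.5. Base `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic 31-bit substream seed derived from a root seed, a stage
# label and an index, so per-question regeneration is stable.
substream_seed <- function(root, stage, index = 0L) {
  h <- sum(utf8ToInt(stage)) %% 1000
  as.integer((as.numeric(root) * 7919 + h * 104729 + as.numeric(index) * 131) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
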