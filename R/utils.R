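# Internal helpers shared across modules.

# Signalled condition classes:
#   silacsig_format_error       - malformed table structure (missing columns)
#   silacsig_validation_error   - row-level value violations
#   silacsig_config_error       - invalid configuration field
#   silacsig_insufficient_data  - not enough quantified observations
.stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "silacsig_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Channel naming: "ML" = medium/light (5 min vs control),
#                 "HL" = heavy/light (15 min vs control).
.channel_prefix <- function(channel) {
  channel <- match.arg(channel, c("ML", "HL"))
  if (channel == "ML") "Ratio.M.L.rep" else "Ratio.H.L.rep"
}

.ratio_cols <- function(x, channel) {
  prefix <- .channel_prefix(channel)
  cols <- grep(paste0("^", gsub(".", "\\.", prefix, fixed = TRUE), "[0-9]+$"),
               names(x), value = TRUE)
  idx <- as.integer(sub(prefix, "", cols, fixed = TRUE))
  cols[order(idx)]
}

# Linear-scale ratio matrix (rows = records, cols = replicates) for a channel.
.ratio_matrix <- function(x, channel) {
  cols <- .ratio_cols(x, channel)
  if (length(cols) == 0L)
    .stop("silacsig_format_error",
          "no '%s*' ratio columns found", .channel_prefix(channel))
  m <- as.matrix(as.data.frame(lapply(x[cols], as.numeric)))
  dimnames(m) <- list(x$Protein.ID, cols)
  m
}

# Per-record median log2 ratio across replicates; NA when nothing quantified.
.median_log2 <- function(x, channel) {
  m <- log2(.ratio_matrix(x, channel))
  apply(m, 1L, function(v) if (all(is.na(v))) NA_real_ else
    stats::median(v, na.rm = TRUE))
}

# Number of replicates with a linear ratio >= threshold.
.replicate_support <- function(x, channel, threshold) {
  m <- .ratio_matrix(x, channel)
  rowSums(m >= threshold, na.rm = TRUE)
}

.n_replicates <- function(x) {
  max(length(.ratio_cols(x, "ML")), length(.ratio_cols(x, "HL")))
}

.check_proportion <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1)
    .stop("silacsig_config_error", "'%s' must be a single value in [0, 1]",
          name)
  invisible(value)
}

.check_nonneg <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value < 0)
    .stop("silacsig_config_error", "'%s' must be a single non-negative value",
          name)
  invisible(value)
}

.check_count <- function(value, name, min = 1L) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < min || value != round(value))
    .stop("silacsig_config_error", "'%s' must be an integer >= %d", name, min)
  invisible(as.integer(value))
}
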