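# Internal helpers shared across modules.

#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom purrr map map_dbl map_int map_chr
NULL

# Derive a per-component seed from a root seed and a counter.
# Kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter * 10007) %% 2147483629L)
}

# Convert a wide abundance tibble (protein + one column per sample) to a
# numeric matrix with protein row names.
abundance_matrix <- function(data) {
  stopifnot(is.data.frame(data), "protein" %in% names(data))
  m <- as.matrix(data[setdiff(names(data), "protein")])
  if (!is.numeric(m)) abort("abundance columns must be numeric")
  rownames(m) <- data$protein
  m
}

# Inverse of abundance_matrix(); preserves the provenance attribute of a
# template tibble when given.
matrix_to_tibble <- function(m, template = NULL) {
  out <- tibble(protein = rownames(m))
  out <- bind_cols(out, as_tibble(m, .name_repair = "minimal"))
  if (!is.null(template)) attr(out, "steps") <- attr(template, "steps")
  out
}

# Append a provenance entry to an abundance tibble.
add_step <- function(data, step) {
  attr(data, "steps") <- c(attr(data, "steps"), step)
  data
}

#' Provenance log of an abundance table
#'
#' Preprocessing functions record the transforms they applied as a character
#' vector attribute; this accessor returns it (or `character(0)`).
#'
#' @param data wide abundance tibble as returned by the preprocessing steps.
#' @return character vector of applied steps, oldest first.
#' @export
provenance <- function(data) {
  attr(data, "steps") %||% character(0)
}

check_meta <- function(meta) {
  need <- c("sample_id", "condition", "day", "bio_rep", "tech_rep")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0) {
    abort(paste0("sample metadata is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(meta)
}

# Align a metadata tibble with the sample columns of an abundance tibble.
align_meta <- function(data, meta) {
  check_meta(meta)
  samples <- setdiff(names(data), "protein")
  if (!all(samples %in% meta$sample_id)) {
    abort("metadata does not describe every sample column")
  }
  meta[match(samples, meta$sample_id), , drop = FALSE]
}

#' Adjusted Rand index between two labellings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to score recovery of planted profile archetypes.
#'
#' @param x,y label vectors of equal length.
#' @return numeric scalar; 1 for identical partitions, ~0 for random ones.
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have the same length")
  tab <- table(x, y)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  n <- length(x)
  sum_ij <- comb2(as.vector(tab))
  sum_a <- comb2(rowSums(tab))
  sum_b <- comb2(colSums(tab))
  expected <- sum_a * sum_b / (n * (n - 1) / 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
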