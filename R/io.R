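# Readers and writers for the plain-text formats the pipeline exchanges:
# abundance/metadata TSV, STRING-style protein-links edge lists, and GMT
# annotation collections.

#' Write / read a wide abundance table as TSV
#'
#' Rows are proteins (first column `protein`), remaining columns one sample
#' each; missing entries are empty fields.
#'
#' @param data wide abundance tibble.
#' @param path file path.
#' @return `write_abundance_tsv()` returns `path` invisibly;
#'   `read_abundance_tsv()` returns the tibble.
#' @export
write_abundance_tsv <- function(data, path) {
  readr::write_tsv(data, path, na = "")
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA"))
}

#' Write / read the sample-metadata sidecar TSV
#'
#' Columns: sample_id, condition, day, bio_rep, tech_rep.
#'
#' @param meta sample metadata tibble.
#' @param path file path.
#' @export
write_sample_meta_tsv <- function(meta, path) {
  check_meta(meta)
  readr::write_tsv(meta, path)
  invisible(path)
}

#' @rdname write_sample_meta_tsv
#' @export
read_sample_meta_tsv <- function(path) {
  check_meta(readr::read_tsv(path, show_col_types = FALSE))
}

#' Read a STRING-style protein-links file into a scored network
#'
#' Expects a whitespace-delimited file with columns
#' `protein1 protein2 combined_score`. The score scale is auto-detected:
#' values above 1 are treated as STRING's 0-999 integers and divided by
#' 1000, otherwise they are taken as 0-1 decimals. Self-loops are dropped,
#' duplicate (A-B / B-A) rows are merged keeping the larger score, and only
#' edges with score >= `score_threshold` are kept (low-confidence
#' interactions below the threshold are removed).
#'
#' @param path path to a plain or gzip-compressed links file.
#' @param score_threshold minimum combined score in [0, 1] an edge must
#'   reach to be kept; default 0.5.
#' @return an undirected simple igraph with a `combined_score` edge
#'   attribute; attributes `n_self_loops` and `score_scale` record parsing
#'   decisions.
#' @export
read_string_links <- function(path, score_threshold = 0.5) {
  if (score_threshold < 0 || score_threshold > 1) {
    abort("score_threshold must be in [0, 1]")
  }
  df <- tryCatch(
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE),
    error = function(e) abort(paste0("malformed links file: ", conditionMessage(e)))
  )
  if (ncol(df) < 3) abort("links file needs 3 columns: protein1 protein2 combined_score")
  names(df)[1:3] <- c("protein1", "protein2", "combined_score")
  score <- suppressWarnings(as.numeric(df$combined_score))
  if (anyNA(score)) {
    abort(paste0("non-numeric combined_score at line ",
                 which(is.na(score))[1] + 1L))
  }
  if (any(score < 0) || any(score > 999)) {
    abort("unknown score scale: combined_score outside [0, 999]")
  }
  scale <- if (any(score > 1)) "integer-0-999" else "decimal-0-1"
  if (scale == "integer-0-999") score <- score / 1000
  df$combined_score <- score

  self <- df$protein1 == df$protein2
  df <- df[!self & df$combined_score >= score_threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(combined_score = "max"))
  attr(g, "n_self_loops") <- sum(self)
  attr(g, "score_scale") <- scale
  g
}

#' Write a network as a STRING-dialect links TSV
#'
#' Scores are written as 0-999 integers, one undirected edge per row with a
#' `protein1 protein2 combined_score` header, so the file round-trips
#' through [read_string_links()].
#'
#' @param net igraph with a `combined_score` edge attribute.
#' @param path file path.
#' @export
write_string_links <- function(net, path) {
  el <- igraph::as_edgelist(net)
  df <- data.frame(protein1 = el[, 1], protein2 = el[, 2],
                   combined_score = as.integer(round(
                     pmin(igraph::E(net)$combined_score, 0.999) * 1000)))
  utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write GMT annotation collections
#'
#' `read_gmt()` parses the tab-delimited GMT dialect (term, description,
#' then member ids) into a named list of id vectors; `write_gmt()` is its
#' inverse.
#'
#' @param path file path.
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of term descriptions.
#' @return `read_gmt()`: named list of protein-id vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("sets must be a named list")
  }
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
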