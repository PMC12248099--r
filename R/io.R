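#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment of a p-value vector. Missing
#' entries propagate as missing and are excluded from the number of tests;
#' q-values are monotone after sorting by p and capped at 1.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  pvals <- as.numeric(pvals)
  ok <- !is.na(pvals)
  bad <- which(ok & (pvals < 0 | pvals > 1))
  if (length(bad)) {
    stop("p-value outside [0, 1] at index ", bad[1L], call. = FALSE)
  }
  out <- rep(NA_real_, length(pvals))
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}

#' Indices discovered at a given false discovery rate
#'
#' @param q q-values (e.g. from [bh_adjust()]).
#' @param fdr target false discovery rate in (0, 1).
#' @return integer vector of indices with `q <= fdr` (NAs never
#'   discovered).
#' @export
discoveries <- function(q, fdr = 0.1) {
  stopifnot(fdr > 0, fdr < 1)
  which(!is.na(q) & q <= fdr)
}

#' Read a delimited profile matrix
#'
#' Reads observations-by-genes delimited text (comma or tab, sniffed from
#' the first line); a header row of gene identifiers is required. When a
#' gene list is given the columns are inner-joined to it, preserving the
#' list's order, and dropped genes are reported.
#'
#' @param file path to the delimited file.
#' @param genes optional character vector of gene identifiers to align to.
#' @return numeric matrix with gene identifiers as column names.
#' @export
read_profile_matrix <- function(file, genes = NULL) {
  sep <- sniff_sep(file)
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "#")
  mat <- as.matrix(df)
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df, is.numeric, logical(1L)))[1L]
    stop("non-numeric values in column '", names(df)[bad], "' of ", file,
         call. = FALSE)
  }
  if (!is.null(genes)) mat <- align_genes(mat, genes, file, margin = 2L)
  mat
}

#' Read a gene-embedding matrix
#'
#' Reads delimited text (comma or tab, sniffed) whose first column holds
#' gene identifiers and remaining columns numeric embedding coordinates; a
#' header line is detected automatically. Rows are inner-joined, order
#' preserved, to an optional gene list.
#'
#' @inheritParams read_profile_matrix
#' @return numeric matrix with gene identifiers as row names.
#' @export
read_embeddings <- function(file, genes = NULL) {
  sep <- sniff_sep(file)
  first <- strsplit(readLines(file, n = 1L), sep, fixed = TRUE)[[1L]]
  has_header <- length(first) > 1L &&
    all(is.na(suppressWarnings(as.numeric(first[-1L]))))
  df <- utils::read.table(file, header = has_header, sep = sep,
                          check.names = FALSE, comment.char = "#",
                          colClasses = c("character", rep(NA, length(first) - 1L)))
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicate gene identifiers in ", file,
                               call. = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("malformed numeric value in ", file, call. = FALSE)
  rownames(mat) <- ids
  if (!is.null(genes)) mat <- align_genes(mat, genes, file, margin = 1L)
  mat
}

#' Read a scalar test panel
#'
#' Accepts either a long-format replicate table with columns
#' `gene, condition, value` (condition taking two levels; extra columns
#' such as a replicate index are ignored) or a precomputed panel table with
#' columns `gene, y, sigma_hat, n1, n2`. Comma or tab delimited, sniffed.
#'
#' @param file path to the delimited file.
#' @return a `"scalar_panel"` object.
#' @export
read_panel <- function(file) {
  sep <- sniff_sep(file)
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "#")
  nms <- tolower(names(df))
  if (all(c("gene", "y", "sigma_hat", "n1", "n2") %in% nms)) {
    names(df) <- nms
    return(scalar_panel(df$y, df$sigma_hat, df$n1[1L], df$n2[1L],
                        genes = as.character(df$gene)))
  }
  if (all(c("gene", "condition", "value") %in% nms)) {
    names(df) <- nms
    conds <- sort(unique(df$condition))
    if (length(conds) != 2L) stop("long-format panel needs exactly two ",
                                  "conditions", call. = FALSE)
    genes <- unique(as.character(df$gene))
    to_mat <- function(cond) {
      sub <- df[df$condition == cond, ]
      counts <- table(sub$gene)
      if (length(unique(counts)) != 1L) {
        stop("unbalanced replicate counts within condition '", cond, "'",
             call. = FALSE)
      }
      vapply(genes, function(g) sub$value[sub$gene == g],
             numeric(counts[[1L]]))
    }
    return(difference_scores(to_mat(conds[1L]), to_mat(conds[2L])))
  }
  stop("unrecognized panel format in ", file,
       ": need columns (gene, condition, value) or (gene, y, sigma_hat, n1, n2)",
       call. = FALSE)
}

#' Write a results table
#'
#' Writes a data frame as tab-separated text with commented provenance
#' header lines (package version, seed, configuration hash). The data body
#' is bitwise reproducible for a fixed seed; only the timestamp comment
#' varies.
#'
#' @param results a data frame.
#' @param file output path.
#' @param seed the seed the run used (recorded in the header).
#' @param config optional list of run parameters; a short hash is recorded.
#' @return `file`, invisibly.
#' @export
write_results <- function(results, file, seed = NULL, config = NULL) {
  stopifnot(is.data.frame(results))
  hdr <- c(
    paste0("# fabgene ", as.character(utils::packageVersion("fabgene"))),
    paste0("# seed: ", if (is.null(seed)) "NA" else format(seed)),
    paste0("# config: ", config_hash(config)),
    paste0("# written: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read back a results table written by [write_results()]
#'
#' @param file path written by [write_results()].
#' @return a data frame (provenance comments skipped).
#' @export
read_results <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE)
}

# --- internal -------------------------------------------------------------

sniff_sep <- function(file) {
  first <- readLines(file, n = 1L)
  if (!length(first)) stop("empty file: ", file, call. = FALSE)
  n_tab <- lengths(regmatches(first, gregexpr("\t", first)))
  n_com <- lengths(regmatches(first, gregexpr(",", first)))
  if (n_tab >= n_com && n_tab > 0) "\t" else ","
}

align_genes <- function(mat, genes, file, margin) {
  have <- if (margin == 1L) rownames(mat) else colnames(mat)
  if (is.null(have)) stop("no gene identifiers found in ", file,
                          call. = FALSE)
  keep <- genes[genes %in% have]
  missing <- setdiff(genes, have)
  if (length(missing)) {
    warning(length(missing), " requested gene(s) absent from ", file, ": ",
            paste(utils::head(missing, 5L), collapse = ", "),
            if (length(missing) > 5L) ", ..." else "", call. = FALSE)
  }
  if (length(keep) < 2L) {
    stop("gene join with ", file, " retains fewer than 2 genes",
         call. = FALSE)
  }
  if (margin == 1L) mat[keep, , drop = FALSE] else mat[, keep, drop = FALSE]
}

config_hash <- function(config) {
  if (is.null(config)) return("none")
  txt <- paste(deparse(config), collapse = "")
  # small portable polynomial hash; provenance only, not cryptographic
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
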