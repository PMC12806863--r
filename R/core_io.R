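#' @keywords internal
"_PACKAGE"

# ---- domain types ----------------------------------------------------------
#
# An expression matrix is a plain numeric matrix, samples in rows, genes in
# columns, with unique column names (gene ids) and row names (sample ids).
# Score matrices over regulators use the gene_roster ordering throughout.

#' Assemble a transcription-factor / target-gene roster
#'
#' Partitions the genes of an expression matrix into an ordered set of
#' transcription factors (TFs, the admissible regulators) and an ordered set
#' of target genes (TGs, regulated only). Every directed score matrix in the
#' package is indexed by this roster: rows are TFs, columns are the TFs
#' followed by the TGs. Admissible directed pairs are all TF-TF and TF-TG
#' pairs excluding self-pairs; TG-TG pairs are never scored.
#'
#' @param tfs character vector of TF gene identifiers (order is kept).
#' @param gene_ids character vector of all gene identifiers, e.g.
#'   `colnames()` of the expression matrix. Genes not in `tfs` become targets.
#' @return An object of class `gene_roster`: a list with elements `tfs`,
#'   `targets` and `all` (TFs first, then targets).
#' @examples
#' gene_roster(c("tf1", "tf2"), c("tf1", "tf2", "g1", "g2"))
#' @export
gene_roster <- function(tfs, gene_ids) {
  tfs <- as.character(tfs)
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(tfs))
    stop("duplicate TF identifiers: ",
         paste(unique(tfs[duplicated(tfs)]), collapse = ", "))
  missing <- setdiff(tfs, gene_ids)
  if (length(missing))
    stop("TFs absent from the expression matrix: ",
         paste(missing, collapse = ", "))
  targets <- setdiff(gene_ids, tfs)
  structure(list(tfs = tfs, targets = targets, all = c(tfs, targets)),
            class = "gene_roster")
}

#' @export
print.gene_roster <- function(x, ...) {
  cat("gene_roster:", length(x$tfs), "TFs,", length(x$targets), "targets,",
      n_admissible_pairs(x), "admissible directed pairs\n")
  invisible(x)
}

#' Number of admissible directed pairs for a roster
#'
#' All ordered TF-TF and TF-TG pairs minus self-pairs:
#' `|F| * (|F| + |G| - 1)`.
#'
#' @param roster a [gene_roster()].
#' @return integer count.
#' @export
n_admissible_pairs <- function(roster) {
  nf <- length(roster$tfs)
  nf * (nf + length(roster$targets) - 1L)
}

# ---- expression I/O --------------------------------------------------------

#' Read a tab-separated expression matrix
#'
#' Expects the DREAM-challenge dialect: a header row of gene identifiers,
#' then one row per sample of tab-separated expression values. Row names
#' (sample ids) are generated as `sample_1 ...` unless the file carries a
#' leading id column (detected when the header has one field fewer than the
#' data rows).
#'
#' @param path file path.
#' @param transpose set `TRUE` if the file stores genes in rows.
#' @return numeric matrix, samples x genes, with gene ids as column names.
#' @export
read_expression <- function(path, transpose = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("expression file needs a header row and at least one sample row: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  widths <- lengths(body)
  has_ids <- all(widths == length(header) + 1L)
  if (!has_ids) {
    bad <- which(widths != length(header))
    if (length(bad))
      stop("ragged expression file: row ", bad[1L] + 1L, " has ",
           widths[bad[1L]], " fields, expected ", length(header))
  }
  sample_ids <- if (has_ids) vapply(body, `[[`, "", 1L) else
    paste0("sample_", seq_along(body))
  cells <- if (has_ids) lapply(body, `[`, -1L) else body
  vals <- suppressWarnings(vapply(cells, as.numeric, numeric(length(header))))
  if (length(header) == 1L) vals <- matrix(vals, nrow = 1L)
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric expression value at data row ", idx[2L],
         ", gene column ", idx[1L], " (", header[idx[1L]], ")")
  }
  m <- t(vals)
  dimnames(m) <- list(sample_ids, header)
  if (transpose) m <- t(m)   # file stored genes in rows; dimnames swap too
  validate_expression(m)
  m
}

#' Write an expression matrix in the tab-separated dialect
#'
#' @param m samples x genes numeric matrix with gene column names.
#' @param path output path.
#' @export
write_expression <- function(m, path) {
  validate_expression(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(m), collapse = "\t"), con)
  apply_fmt <- function(row) paste(formatC(row, format = "g", digits = 17),
                                   collapse = "\t")
  writeLines(vapply(seq_len(nrow(m)), function(i) apply_fmt(m[i, ]), ""), con)
  invisible(NULL)
}

validate_expression <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression must be a numeric matrix (samples x genes)")
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("expression matrix needs at least 2 samples and 2 genes")
  if (anyNA(m) || any(!is.finite(m)))
    stop("expression matrix contains missing or non-finite values")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop("expression matrix needs unique gene column names")
  invisible(m)
}

#' Read a transcription-factor list
#'
#' One gene identifier per line; blank lines ignored. Matching against the
#' expression matrix is exact and case-sensitive.
#'
#' @param path file path.
#' @return character vector of TF ids.
#' @export
read_tf_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

# ---- gold standard ---------------------------------------------------------

#' Read a gold-standard edge list
#'
#' Tab-separated `regulator<TAB>target<TAB>label` with label 0 or 1. A
#' missing third column is read as all-1 (positives only). Self-pairs,
#' regulators outside the TF set and TG-TG pairs are rejected.
#'
#' @param path file path.
#' @param roster a [gene_roster()] defining the admissible pair universe.
#' @return object of class `gold_standard`: list with `edges` (data.frame
#'   regulator/target/label), `positives` (character key vector), and counts
#'   `P`, `N`, `T` over the admissible universe.
#' @export
read_gold_standard <- function(path, roster) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          col.names = c("regulator", "target", "label")[1:3],
                          fill = TRUE)
  if (ncol(df) < 3L || all(!nzchar(df[[3L]]))) df$label <- "1"
  df$label <- as.integer(df$label)
  gold_standard(df[df$label == 1L, c("regulator", "target")], roster)
}

#' Construct a gold standard from a positive edge data frame
#'
#' @param positives data.frame with columns `regulator`, `target` listing the
#'   true directed edges.
#' @param roster a [gene_roster()].
#' @return a `gold_standard` object (see [read_gold_standard()]).
#' @export
gold_standard <- function(positives, roster) {
  stopifnot(inherits(roster, "gene_roster"))
  reg <- as.character(positives$regulator)
  tgt <- as.character(positives$target)
  if (any(reg == tgt)) stop("gold standard contains self-pairs")
  bad_reg <- setdiff(reg, roster$tfs)
  if (length(bad_reg))
    stop("gold-standard regulators outside the TF set: ",
         paste(unique(bad_reg), collapse = ", "))
  bad_tgt <- setdiff(tgt, roster$all)
  if (length(bad_tgt))
    stop("gold-standard targets outside the roster: ",
         paste(unique(bad_tgt), collapse = ", "))
  key <- paste(reg, tgt, sep = "\r")
  if (anyDuplicated(key)) {
    keep <- !duplicated(key)
    reg <- reg[keep]; tgt <- tgt[keep]; key <- key[keep]
  }
  T_all <- n_admissible_pairs(roster)
  P <- length(key)
  structure(list(edges = data.frame(regulator = reg, target = tgt,
                                    label = rep(1L, P)),
                 positives = key, P = P, N = T_all - P, T = T_all,
                 roster = roster),
            class = "gold_standard")
}

#' Write a gold standard as TSV
#'
#' Emits `regulator<TAB>target<TAB>1` for every positive edge.
#'
#' @param gold a `gold_standard`.
#' @param path output path.
#' @export
write_gold_standard <- function(gold, path) {
  utils::write.table(gold$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("gold_standard: P =", x$P, "positives of T =", x$T,
      "admissible pairs\n")
  invisible(x)
}

# ---- ranked edge lists -----------------------------------------------------

#' Construct a ranked edge list
#'
#' @param regulator,target,score parallel vectors of directed scored edges.
#' @return data.frame of class `ranked_edges`, sorted by decreasing score
#'   with lexicographic `(regulator, target)` tie-break.
#' @export
ranked_edges <- function(regulator, target, score) {
  regulator <- as.character(regulator)
  target <- as.character(target)
  score <- as.numeric(score)
  if (any(regulator == target)) stop("ranked edge list contains self-pairs")
  key <- paste(regulator, target, sep = "\r")
  if (anyDuplicated(key)) stop("ranked edge list contains duplicate pairs")
  ord <- order(-score, regulator, target, method = "radix")
  structure(data.frame(regulator = regulator[ord], target = target[ord],
                       score = score[ord], stringsAsFactors = FALSE),
            class = c("ranked_edges", "data.frame"))
}

#' Write a ranked edge list (DREAM prediction dialect)
#'
#' One line per edge, `regulator<TAB>target<TAB>score`, order preserved.
#'
#' @param edges a [ranked_edges()] data frame.
#' @param path output path.
#' @export
write_ranked_edges <- function(edges, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(edges))
    writeLines(paste(edges$regulator, edges$target,
                     formatC(edges$score, format = "g", digits = 17),
                     sep = "\t"), con)
  invisible(NULL)
}

#' Read a ranked edge list
#'
#' @param path file path of a `regulator<TAB>target<TAB>score` TSV.
#' @return a `ranked_edges` data frame (order of the file is validated to be
#'   non-increasing in score).
#' @export
read_ranked_edges <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(structure(data.frame(regulator = character(), target = character(),
                                score = numeric()),
                     class = c("ranked_edges", "data.frame")))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("ranked edge file rows must have 3 tab-separated fields")
  df <- data.frame(regulator = vapply(parts, `[[`, "", 1L),
                   target = vapply(parts, `[[`, "", 2L),
                   score = as.numeric(vapply(parts, `[[`, "", 3L)),
                   stringsAsFactors = FALSE)
  if (is.unsorted(rev(df$score)))
    stop("ranked edge file scores are not non-increasing")
  structure(df, class = c("ranked_edges", "data.frame"))
}

# ---- standardization -------------------------------------------------------

#' Z-score standardize an expression matrix
#'
#' Centers and scales every gene column to mean 0 and unit *population*
#' standard deviation (denominator `m`, the number of samples, not `m - 1`).
#' The standardized matrix is the input to all downstream stages.
#'
#' @param m samples x genes numeric matrix.
#' @return matrix of the same shape; each column has mean 0 and population
#'   standard deviation 1.
#' @examples
#' m <- cbind(g1 = c(1, 2, 3), g2 = c(4, 1, 1))
#' rownames(m) <- paste0("s", 1:3)
#' zscore_normalize(m)
#' @export
zscore_normalize <- function(m) {
  validate_expression(m)
  mu <- colMeans(m)
  centered <- sweep(m, 2L, mu)
  sd_pop <- sqrt(colMeans(centered^2))
  zero <- sd_pop <= 0
  if (any(zero))
    stop("constant expression column(s), cannot z-score: ",
         paste(colnames(m)[zero], collapse = ", "))
  sweep(centered, 2L, sd_pop, `/`)
}
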