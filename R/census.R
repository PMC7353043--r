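# Zero-expression census of a gene set on sparse single-cell count matrices.

#' Adenylyl cyclase gene symbols
#'
#' The ten adenylyl cyclase isoform genes, in the human (`ADCY1`..`ADCY10`)
#' or mouse (`Adcy1`..`Adcy10`) symbol dialect.
#'
#' @param species `"human"` or `"mouse"`.
#' @return Character vector of 10 gene symbols.
#' @export
#' @examples
#' adcy_genes("mouse")
adcy_genes <- function(species = c("human", "mouse")) {
  species <- match.arg(species)
  base <- paste0("ADCY", 1:10)
  if (species == "mouse") paste0("Adcy", 1:10) else base
}

#' Sparse gene-by-cell count matrix
#'
#' @param counts non-negative integer matrix or `Matrix` sparse matrix,
#'   genes in rows, cells in columns.
#' @param genes gene symbols (unique), one per row.
#' @param barcodes cell barcodes, one per column.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts, genes, barcodes) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "dMatrix")
  if (length(genes) != nrow(counts) || length(barcodes) != ncol(counts))
    stopf("genes/barcodes do not match the matrix dimensions")
  if (anyDuplicated(genes)) stopf("gene symbols must be unique")
  v <- counts@x
  if (any(v < 0) || any(v != floor(v)))
    stopf("counts must be non-negative integers")
  rownames(counts) <- genes
  colnames(counts) <- barcodes
  structure(list(genes = as.character(genes),
                 barcodes = as.character(barcodes), counts = counts),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells, %.2f%% nonzero\n",
              nrow(x$counts), ncol(x$counts),
              100 * Matrix::nnzero(x$counts) / prod(dim(x$counts))))
  invisible(x)
}

#' Census of cells lacking expression of a whole gene set
#'
#' Counts the cells whose counts are zero for *every* gene of the set —
#' "lacking expression" means a count of exactly 0, the presence/absence
#' filter of a count-matrix browser, not a low-count threshold.
#'
#' @param matrix a [count_matrix()].
#' @param gene_set gene symbols to census (non-empty).
#' @param match_mode `"strict"` (exact symbols) or `"case_insensitive"`
#'   (matches `ADCY1` to `Adcy1`).
#' @param allow_missing if `TRUE`, genes of the set absent from the matrix
#'   are warned about and treated as all-zero; if `FALSE` (default) any
#'   missing gene is an error.
#' @return Object of class `census_result`: list with `n_zero`, `n_total`,
#'   `percent` (one decimal, round-half-up), `genes_used`, `genes_missing`
#'   and `per_gene_positive` (named vector: cells with >= 1 count per gene).
#' @export
#' @examples
#' m <- simulate_count_matrix(100, adcy_genes(), frac_zero = 0.6, seed = 1)
#' zero_expression_census(m, adcy_genes())$percent
zero_expression_census <- function(matrix, gene_set,
                                   match_mode = c("strict", "case_insensitive"),
                                   allow_missing = FALSE) {
  stopifnot(inherits(matrix, "count_matrix"))
  match_mode <- match.arg(match_mode)
  if (length(gene_set) == 0) stopf("empty gene_set: a vacuous census is meaningless")
  hit <- if (match_mode == "strict") match(gene_set, matrix$genes)
  else match(toupper(gene_set), toupper(matrix$genes))
  missing <- gene_set[is.na(hit)]
  if (length(missing)) {
    if (!allow_missing)
      stopf("gene(s) not in the matrix: %s", paste(missing, collapse = ", "))
    warnf("treating missing gene(s) as all-zero: %s",
          paste(missing, collapse = ", "))
  }
  rows <- hit[!is.na(hit)]
  if (length(rows) == 0) stopf("no gene of the set is present in the matrix")
  sub <- matrix$counts[rows, , drop = FALSE]
  pos_per_cell <- Matrix::colSums(sub > 0)
  n_zero <- sum(pos_per_cell == 0)
  n_total <- ncol(sub)
  structure(list(n_zero = as.integer(n_zero), n_total = as.integer(n_total),
                 percent = round_half_up(100 * n_zero / n_total, 1),
                 genes_used = matrix$genes[rows], genes_missing = missing,
                 per_gene_positive = stats::setNames(Matrix::rowSums(sub > 0),
                                                     matrix$genes[rows])),
            class = "census_result")
}

#' @export
print.census_result <- function(x, ...) {
  cat(sprintf("census: %d of %d cells (%.1f%%) lack all %d gene(s)\n",
              x$n_zero, x$n_total, x$percent, length(x$genes_used)))
  invisible(x)
}

#' Simulate a count matrix with a controlled zero-expression fraction
#'
#' Exactly `round(n_cells * frac_zero)` cells (round-half-up, seeded choice)
#' have zero counts across the whole `gene_set`; every other cell has at
#' least one count on at least one set gene. Set-gene counts follow a
#' zero-inflated Poisson per gene; background genes carry plain Poisson
#' noise.
#'
#' @param n_cells number of cells.
#' @param gene_set gene symbols whose joint zero-expression is controlled.
#' @param frac_zero fraction of cells with no set-gene expression.
#' @param n_background_genes extra noise genes.
#' @param lambda_set Poisson mean of expressed set-gene counts.
#' @param dropout zero-inflation probability per set gene in expressing
#'   cells.
#' @param lambda_bg Poisson mean of background-gene counts.
#' @param seed integer seed.
#' @return A [count_matrix()].
#' @export
simulate_count_matrix <- function(n_cells, gene_set = adcy_genes(),
                                  frac_zero = 0.5, n_background_genes = 50,
                                  lambda_set = 0.8, dropout = 0.6,
                                  lambda_bg = 0.3, seed = 1L) {
  if (!is_frac(frac_zero)) stopf("frac_zero must lie in [0, 1]")
  if (!is_count(n_cells)) stopf("n_cells must be a positive integer")
  n_set <- length(gene_set)
  if (n_set == 0) stopf("gene_set must be non-empty")
  with_seed(seed, {
    k_zero <- round_half_up(n_cells * frac_zero)
    zero_cells <- sample.int(n_cells, k_zero)
    expressing <- setdiff(seq_len(n_cells), zero_cells)
    i <- integer(0); j <- integer(0); v <- integer(0)
    for (g in seq_len(n_set)) {
      drawn <- stats::rpois(length(expressing), lambda_set) *
        (stats::runif(length(expressing)) > dropout)
      nz <- drawn > 0
      i <- c(i, rep.int(g, sum(nz)))
      j <- c(j, expressing[nz])
      v <- c(v, drawn[nz])
    }
    # guarantee every expressing cell has >= 1 set-gene count
    tot <- numeric(n_cells)
    if (length(j)) tot[unique(j)] <- 1
    need <- expressing[tot[expressing] == 0]
    if (length(need)) {
      g_fix <- sample.int(n_set, length(need), replace = TRUE)
      i <- c(i, g_fix); j <- c(j, need); v <- c(v, rep.int(1L, length(need)))
    }
    bg_names <- sprintf("BG%04d", seq_len(n_background_genes))
    if (n_background_genes > 0) {
      drawn <- stats::rpois(n_background_genes * n_cells, lambda_bg)
      nz <- which(drawn > 0)
      i <- c(i, n_set + ((nz - 1L) %% n_background_genes) + 1L)
      j <- c(j, ((nz - 1L) %/% n_background_genes) + 1L)
      v <- c(v, drawn[nz])
    }
    counts <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(v),
                                   dims = c(n_set + n_background_genes, n_cells))
    count_matrix(counts, c(gene_set, bg_names),
                 sprintf("cell%06d", seq_len(n_cells)))
  })
}

#' Write / read a count matrix as a MatrixMarket triplet directory
#'
#' Cellranger-style layout: `matrix.mtx`, `genes.tsv` (two columns: id and
#' symbol) and `barcodes.tsv`.
#'
#' @param matrix a [count_matrix()].
#' @param dir directory (created if needed).
#' @return `write_count_matrix` returns `dir` invisibly;
#'   `read_count_matrix` a [count_matrix()].
#' @export
write_count_matrix <- function(matrix, dir) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(matrix$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(id = matrix$genes, symbol = matrix$genes),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(matrix$barcodes, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  count_matrix(counts, genes[[2]], barcodes)
}
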