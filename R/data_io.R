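# Readers/writers for the external table formats: expression matrices,
# STRING-style PPI edge lists, essentiality screens, drug-target maps,
# synthetic-lethal pair lists and drug-combination Bliss records.
# Gene identity throughout the package is the uppercased symbol string.

#' Construct an expression matrix object
#'
#' @param values numeric gene x sample matrix (log2 scale) with gene symbols as
#'   row names and sample ids as column names.
#' @param condition one of `"tumor"`, `"normal"`, `"cellline"`.
#' @return An object of class `dscn_expr` with fields `genes`, `samples`,
#'   `values`, `condition`.
#' @export
expression_matrix <- function(values, condition = c("tumor", "normal", "cellline")) {
  condition <- match.arg(condition)
  if (!is.matrix(values) || !is.numeric(values)) {
    dscn_input_error("expression values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    dscn_input_error("expression matrix needs gene row names and sample column names")
  }
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values))) {
    dscn_input_error("duplicate gene symbols in expression matrix")
  }
  if (anyDuplicated(colnames(values))) {
    dscn_input_error("duplicate sample ids in expression matrix")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    dscn_input_error("empty expression matrix")
  }
  ok <- apply(values, 1L, function(r) any(is.finite(r)))
  if (!all(ok)) {
    dscn_input_error(sprintf(
      "expression rows with no finite value: %s",
      paste(rownames(values)[!ok], collapse = ", ")))
  }
  structure(
    list(genes = rownames(values), samples = colnames(values),
         values = values, condition = condition),
    class = "dscn_expr")
}

# sniff tab vs comma on the header line
.sniff_sep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (length(hdr) == 0L) dscn_input_error(sprintf("empty file: %s", path))
  if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
}

.read_gene_table <- function(path) {
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L) dscn_format_error(sprintf("malformed header in %s: need gene column plus >=1 sample", path))
  genes <- toupper(as.character(df[[1L]]))
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & trimws(col) != "" & toupper(trimws(col)) != "NA")
      if (length(bad)) {
        dscn_format_error(sprintf(
          "non-numeric value '%s' at gene %s, column %s in %s",
          col[bad[1L]], genes[bad[1L]], colnames(vals)[j], path))
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  m
}

.collapse_duplicate_rows <- function(m, what) {
  if (anyDuplicated(rownames(m))) {
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    dscn_warn(sprintf("%d duplicated %s row(s) collapsed by mean: %s",
                      length(dup), what, paste(utils::head(dup, 5L), collapse = ", ")))
    grp <- factor(rownames(m), levels = unique(rownames(m)))
    m <- do.call(rbind, lapply(split(seq_len(nrow(m)), grp), function(i) {
      colMeans(m[i, , drop = FALSE], na.rm = TRUE)
    }))
  }
  m
}

#' Read a gene x sample expression table
#'
#' Tab- or comma-delimited text; first column gene symbol, header row of sample
#' ids. Duplicate gene rows are collapsed by their mean with a warning
#' (probe-level microarray duplicates).
#'
#' @param path file path.
#' @param condition condition label (`"tumor"`, `"normal"`, `"cellline"`).
#' @return A [expression_matrix()] object.
#' @export
read_expression <- function(path, condition = c("tumor", "normal", "cellline")) {
  condition <- match.arg(condition)
  m <- .read_gene_table(path)
  m <- .collapse_duplicate_rows(m, "gene")
  expression_matrix(m, condition)
}

#' Write an expression matrix as TSV
#'
#' @param x a `dscn_expr` object.
#' @param path output path.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "dscn_expr"))
  df <- data.frame(gene = x$genes, x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an essentiality table
#'
#' Values are log2 fold changes of cell count after knockout
#' (Project-Achilles-style); more negative means more essential. Inputs are
#' assumed already log2 transformed.
#'
#' @param values numeric gene x cell-line matrix with dimnames.
#' @return `dscn_essentiality` object with fields `genes`, `cell_lines`, `values`.
#' @export
essentiality_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    dscn_input_error("essentiality values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    dscn_input_error("essentiality matrix needs gene and cell-line dimnames")
  }
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values))) dscn_input_error("duplicate genes in essentiality table")
  if (anyDuplicated(colnames(values))) dscn_input_error("duplicate cell lines in essentiality table")
  structure(list(genes = rownames(values), cell_lines = colnames(values), values = values),
            class = "dscn_essentiality")
}

#' Read a gene x cell-line essentiality table
#'
#' @inheritParams read_expression
#' @return An [essentiality_table()] object.
#' @export
read_essentiality <- function(path) {
  m <- .read_gene_table(path)
  m <- .collapse_duplicate_rows(m, "gene")
  essentiality_table(m)
}

#' Read a STRING-style PPI edge list
#'
#' Whitespace/tab-delimited columns `protein1 protein2 combined_score`.
#' Self-loops are dropped, duplicate undirected edges collapsed keeping the
#' maximum score, and edges below `score_min` removed.
#'
#' @param path file path.
#' @param score_min minimum combined score retained (default 400, STRING
#'   medium confidence).
#' @return `dscn_ppi` data.frame with columns `geneA`, `geneB`, `score`.
#' @export
read_ppi <- function(path, score_min = 400) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "")
  if (ncol(df) < 3L) dscn_format_error("PPI file needs columns protein1 protein2 combined_score")
  ppi_edge_list(toupper(as.character(df[[1L]])), toupper(as.character(df[[2L]])),
                as.numeric(df[[3L]]), score_min = score_min)
}

#' Build a validated undirected PPI edge list
#'
#' @param geneA,geneB character vectors of endpoints.
#' @param score numeric combined scores (>= 0).
#' @param score_min minimum score retained.
#' @return `dscn_ppi` data.frame.
#' @export
ppi_edge_list <- function(geneA, geneB, score, score_min = 0) {
  geneA <- toupper(as.character(geneA)); geneB <- toupper(as.character(geneB))
  score <- as.numeric(score)
  if (any(is.na(score)) || any(score < 0)) dscn_format_error("PPI scores must be non-negative numbers")
  keep <- geneA != geneB
  geneA <- geneA[keep]; geneB <- geneB[keep]; score <- score[keep]
  lo <- pmin(geneA, geneB); hi <- pmax(geneA, geneB)
  key <- paste(lo, hi, sep = "\r")
  score <- as.numeric(tapply(score, key, max)[unique(key)])
  first <- !duplicated(key)
  df <- data.frame(geneA = lo[first], geneB = hi[first], score = score,
                   stringsAsFactors = FALSE)
  df <- df[df$score >= score_min, , drop = FALSE]
  if (nrow(df) == 0L) dscn_input_error("no PPI edge survives filtering")
  df <- df[order(df$geneA, df$geneB), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("dscn_ppi", "data.frame")
  df
}

#' Read a drug-target map
#'
#' TSV with columns `drug_id` and `gene` (one row per drug-target link).
#'
#' @param path file path.
#' @return Named list: drug id -> character vector of uppercase target symbols.
#' @export
read_targets <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) dscn_format_error("target file needs columns drug_id, gene")
  tl <- lapply(split(toupper(as.character(df[[2L]])), as.character(df[[1L]])),
               function(g) sort(unique(g[g != ""])))
  empty <- vapply(tl, length, 1L) == 0L
  if (any(empty)) dscn_input_error("drug(s) with empty target set")
  tl
}

#' Read a synthetic-lethal gene-pair table
#'
#' TSV columns `geneA geneB sl_score`; pairs are unordered and deduplicated
#' (maximum score kept); self pairs dropped.
#'
#' @param path file path.
#' @return data.frame with columns `geneA`, `geneB`, `sl_score`.
#' @export
read_sl_pairs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) dscn_format_error("SL pair file needs columns geneA geneB sl_score")
  a <- toupper(as.character(df[[1L]])); b <- toupper(as.character(df[[2L]]))
  s <- as.numeric(df[[3L]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]; s <- s[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  s <- as.numeric(tapply(s, key, max)[unique(key)])
  first <- !duplicated(key)
  out <- data.frame(geneA = lo[first], geneB = hi[first], sl_score = s,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a drug-combination Bliss synergy table
#'
#' TSV columns `drugA drugB cell_line bliss`.
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
read_drug_combos <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 4L) dscn_format_error("drug combo file needs columns drugA drugB cell_line bliss")
  out <- data.frame(drugA = as.character(df[[1L]]), drugB = as.character(df[[2L]]),
                    cell_line = as.character(df[[3L]]), bliss = as.numeric(df[[4L]]),
                    stringsAsFactors = FALSE)
  if (any(out$drugA == out$drugB)) dscn_input_error("drug combination with identical drugs")
  if (any(!is.finite(out$bliss))) dscn_input_error("non-finite Bliss score")
  out
}

#' Write a ranked pair table as TSV
#'
#' Rows are ordered ascending by the pair impact score (`IS_pair`; more
#' negative = more impactful) with a lexicographic `(gene1, gene2)` tiebreak.
#'
#' @param pairs a pair-ranking data.frame as returned by [rank_all_pairs()],
#'   or any data.frame with columns `gene1, gene2, IS_T1, IS_T2_given_T1,
#'   IS_pair, synergy`.
#' @param path output path.
#' @export
write_pair_ranking <- function(pairs, path) {
  cols <- c("gene1", "gene2", "IS_T1", "IS_T2_given_T1", "IS_pair", "synergy")
  if (!all(cols %in% names(pairs))) {
    dscn_input_error(sprintf("pair table missing columns: %s",
                             paste(setdiff(cols, names(pairs)), collapse = ", ")))
  }
  pairs <- pairs[order(pairs$IS_pair, pairs$gene1, pairs$gene2), cols, drop = FALSE]
  names(pairs)[6L] <- "synergy_flag"
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
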