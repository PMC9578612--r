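# Association between observed drug-combination synergy (Bliss score) and
# predicted target-combination synergy: Bliss thresholding, drug-pair to
# target-pair mapping, the 2x2 contingency table of mapping events, the
# Pearson chi-square test and a zero-cell-corrected odds ratio.

#' Classify a drug combination as synergistic by Bliss score
#'
#' Synergistic iff the Bliss score strictly exceeds the threshold
#' (default 0.12).
#'
#' @param bliss finite numeric score(s).
#' @param threshold synergy cutoff.
#' @return logical vector.
#' @export
classify_drug_synergy <- function(bliss, threshold = 0.12) {
  if (any(is.na(bliss))) dscn_input_error("NaN/NA Bliss score")
  bliss > threshold
}

#' Target pairs induced by a drug combination
#'
#' All unordered cross-drug gene pairs {x, y} with x a target of drug A and y
#' a target of drug B, x != y, deduplicated. Empty results (e.g. both drugs
#' share a single target) produce a warning.
#'
#' @param targets_a,targets_b character vectors of target genes.
#' @return two-column character matrix (`gene1` < `gene2`), possibly 0 rows.
#' @export
drug_pair_to_target_pairs <- function(targets_a, targets_b) {
  targets_a <- unique(toupper(targets_a)); targets_b <- unique(toupper(targets_b))
  if (length(targets_a) == 0L || length(targets_b) == 0L) {
    dscn_input_error("empty target set for a drug")
  }
  g <- expand.grid(a = targets_a, b = targets_b, stringsAsFactors = FALSE)
  g <- g[g$a != g$b, , drop = FALSE]
  if (nrow(g) == 0L) {
    dscn_warn("drug pair induces no target pair")
    return(matrix(character(0), 0L, 2L, dimnames = list(NULL, c("gene1", "gene2"))))
  }
  m <- cbind(gene1 = pmin(g$a, g$b), gene2 = pmax(g$a, g$b))
  m <- m[!duplicated(paste(m[, 1L], m[, 2L], sep = "\r")), , drop = FALSE]
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' Construct a 2x2 contingency table object
#'
#' @param a drug-synergy & target-synergy count.
#' @param b drug-synergy & target-non-synergy count.
#' @param c_ non-synergy & target-synergy count.
#' @param d non-synergy & target-non-synergy count.
#' @return `dscn_contingency` object.
#' @export
contingency_table <- function(a, b, c_, d) {
  counts <- c(a = a, b = b, c = c_, d = d)
  if (any(counts < 0) || any(counts %% 1 != 0)) {
    dscn_input_error("contingency counts must be non-negative integers")
  }
  if (sum(counts) < 1) dscn_warn("degenerate all-zero contingency table")
  structure(as.list(counts), class = "dscn_contingency")
}

#' Build the drug-synergy x target-synergy contingency table
#'
#' Each (drug combination, mapped target pair) event contributes one count:
#' rows by drug synergy (Bliss > threshold), columns by the predicted synergy
#' flag of the target pair. A target pair mapped by several drug combinations
#' is counted once per combination.
#'
#' @param combos data.frame as from [read_drug_combos()].
#' @param pair_scores ranking data.frame with columns `gene1, gene2, synergy`
#'   (as from [rank_all_pairs()]).
#' @param targets drug-target list (drug id -> gene vector).
#' @param threshold Bliss synergy cutoff.
#' @return `dscn_contingency`.
#' @export
build_contingency <- function(combos, pair_scores, targets, threshold = 0.12) {
  key <- paste(pair_scores$gene1, pair_scores$gene2, sep = "\r")
  syn <- stats::setNames(pair_scores$synergy, key)
  a <- b <- c_ <- d <- 0L
  unmapped <- 0L
  for (r in seq_len(nrow(combos))) {
    ta <- targets[[combos$drugA[r]]]
    tb <- targets[[combos$drugB[r]]]
    if (is.null(ta) || is.null(tb)) { unmapped <- unmapped + 1L; next }
    pairs <- suppressWarnings(drug_pair_to_target_pairs(ta, tb))
    if (nrow(pairs) == 0L) { unmapped <- unmapped + 1L; next }
    flags <- syn[paste(pairs[, 1L], pairs[, 2L], sep = "\r")]
    flags <- flags[!is.na(flags)]
    if (length(flags) == 0L) { unmapped <- unmapped + 1L; next }
    ds <- classify_drug_synergy(combos$bliss[r], threshold)
    if (ds) {
      a <- a + sum(flags); b <- b + sum(!flags)
    } else {
      c_ <- c_ + sum(flags); d <- d + sum(!flags)
    }
  }
  if (a + b + c_ + d == 0L) dscn_input_error("no drug combination maps to a scored target pair")
  if (unmapped > 0L) {
    dscn_warn(sprintf("%d drug combination(s) had no mappable scored target pair", unmapped))
  }
  contingency_table(a, b, c_, d)
}

#' Pearson chi-square test of a 2x2 table
#'
#' Closed form without continuity correction:
#' X^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)), 1 df.
#'
#' @param tab `dscn_contingency`.
#' @return list with `statistic` and `p_value`.
#' @export
chi_square_test <- function(tab) {
  stopifnot(inherits(tab, "dscn_contingency"))
  a <- tab$a; b <- tab$b; c_ <- tab$c; d <- tab$d
  n <- a + b + c_ + d
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) dscn_input_error("zero margin: chi-square test undefined")
  stat <- n * (a * d - b * c_)^2 / prod(margins)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Odds ratio with add-one zero-cell correction
#'
#' OR = ad / bc; when any cell is zero, every cell gets +1 first
#' (this correction reproduces the reported value on the published table).
#' An all-zero table returns 1 with a warning.
#'
#' @param tab `dscn_contingency`.
#' @return numeric odds ratio (not truncated; use `trunc()` for summaries).
#' @export
odds_ratio <- function(tab) {
  stopifnot(inherits(tab, "dscn_contingency"))
  a <- tab$a; b <- tab$b; c_ <- tab$c; d <- tab$d
  if (a + b + c_ + d == 0) {
    dscn_warn("degenerate all-zero contingency table")
    return(1)
  }
  if (any(c(a, b, c_, d) == 0)) {
    ((a + 1) * (d + 1)) / ((b + 1) * (c_ + 1))
  } else {
    (a * d) / (b * c_)
  }
}
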