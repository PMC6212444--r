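#' Load transposable-element presence/absence calls
#'
#' Reads a T-lex2-style TSV: columns `te_id`, `family`, `arm`, `pos`, then
#' one column per strain with calls `P` (present), `A` (absent) or `-`
#' (missing). Strain columns must match the cohort's strain ids.
#'
#' @param path TSV file.
#' @param strains data.frame `id`, `population` for the cohort.
#' @return list of class `te_table`: `info` (data.frame `te_id`, `family`,
#'   `arm`, `pos`), `calls` (character matrix TEs x strains) and `strains`.
#' @export
load_te_calls <- function(path, strains) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  te_table(tab, strains)
}

#' Build a TE table from a data.frame
#'
#' @param tab data.frame in the layout described in [load_te_calls()].
#' @param strains cohort strain data.frame (`id`, `population`).
#' @return A `te_table`.
#' @export
te_table <- function(tab, strains) {
  meta <- c("te_id", "family", "arm", "pos")
  stopifnot(all(meta %in% names(tab)))
  if (anyDuplicated(tab$te_id)) {
    stop("duplicate te_id: ", tab$te_id[duplicated(tab$te_id)][1])
  }
  strain_cols <- setdiff(names(tab), meta)
  extra <- setdiff(strain_cols, strains$id)
  if (length(extra)) stop("strain column(s) not in cohort: ",
                          paste(extra, collapse = ", "))
  calls <- as.matrix(tab[, strain_cols, drop = FALSE])
  bad <- matrix(!(calls %in% c("P", "A", "-")), nrow(calls))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("unknown call symbol '", calls[w[1], w[2]], "' at TE ",
         tab$te_id[w[1]], ", strain ", strain_cols[w[2]])
  }
  rownames(calls) <- tab$te_id
  structure(list(info = tab[, meta], calls = calls,
                 strains = strains[match(strain_cols, strains$id), ]),
            class = "te_table")
}

#' @export
print.te_table <- function(x, ...) {
  cat(sprintf("te_table: %d TEs x %d strains\n", nrow(x$info),
              ncol(x$calls)))
  invisible(x)
}

#' Classify TEs by population frequency and missingness
#'
#' Per-population presence frequency is presence count / called strains.
#' A TE is `undetermined` when either population's missing-call fraction
#' exceeds `max_missing`; otherwise `fixed_both` when the frequency is
#' exactly 1 among called strains in both populations, `low_freq_both`
#' when the frequency is below `maf_min` in both, else `testable`.
#'
#' @param te a `te_table`.
#' @param maf_min low-frequency cutoff.
#' @param max_missing maximum tolerated missing fraction per population.
#' @return data.frame: `te_id`, `family`, `arm`, `pos`, per-population
#'   `freq_*` and `missing_*`, and `classification`.
#' @export
classify_tes <- function(te, maf_min = 0.05, max_missing = 0.30) {
  stopifnot(inherits(te, "te_table"))
  pops <- unique(te$strains$population)
  stopifnot(length(pops) == 2)
  stat <- lapply(pops, function(p) {
    m <- te$calls[, te$strains$population == p, drop = FALSE]
    called <- rowSums(m != "-")
    list(freq = ifelse(called > 0, rowSums(m == "P") / called, NA_real_),
         missing = rowSums(m == "-") / ncol(m))
  })
  f1 <- stat[[1]]$freq; f2 <- stat[[2]]$freq
  m1 <- stat[[1]]$missing; m2 <- stat[[2]]$missing
  cls <- rep("testable", nrow(te$info))
  cls[which(f1 == 1 & f2 == 1)] <- "fixed_both"
  cls[which(f1 < maf_min & f2 < maf_min)] <- "low_freq_both"
  cls[which(m1 > max_missing | m2 > max_missing | is.na(f1) | is.na(f2))] <-
    "undetermined"
  out <- data.frame(te$info, freq_1 = f1, freq_2 = f2,
                    missing_1 = m1, missing_2 = m2,
                    classification = cls, stringsAsFactors = FALSE)
  names(out)[names(out) == "freq_1"] <- paste0("freq_", pops[1])
  names(out)[names(out) == "freq_2"] <- paste0("freq_", pops[2])
  names(out)[names(out) == "missing_1"] <- paste0("missing_", pops[1])
  names(out)[names(out) == "missing_2"] <- paste0("missing_", pops[2])
  out
}

#' Weir & Cockerham F_ST for testable TEs
#'
#' Encodes presence/absence as homozygous diploid genotypes (present = 1/1,
#' absent = 0/0, missing dropped) - consistent with inbred strains - and
#' evaluates the same variance-component estimator as for SNPs
#' ([site_fst_wc()]). A TE whose calls are entirely missing in one
#' population is reclassified `undetermined`.
#'
#' @param te a `te_table`.
#' @param classified output of [classify_tes()] (recomputed when NULL).
#' @return `classified` with a `theta` column (non-NA only for testable
#'   TEs).
#' @export
te_fst <- function(te, classified = NULL) {
  stopifnot(inherits(te, "te_table"))
  if (is.null(classified)) classified <- classify_tes(te)
  pops <- unique(te$strains$population)
  counts <- lapply(pops, function(p) {
    m <- te$calls[, te$strains$population == p, drop = FALSE]
    cbind(rowSums(m == "A"), 0L, rowSums(m == "P"))
  })
  comp <- site_fst_wc(counts[[1]], counts[[2]])
  theta <- comp$theta
  empty <- rowSums(counts[[1]]) == 0 | rowSums(counts[[2]]) == 0
  classified$classification[empty] <- "undetermined"
  theta[classified$classification != "testable"] <- NA_real_
  classified$theta <- theta
  classified
}

#' Candidate differentiated TEs against SNP critical values
#'
#' The TE F_ST distribution is calibrated on the SNP distribution: a
#' testable TE is a tier-t candidate iff its theta is >= the SNP-derived
#' critical value of its chromosome arm at tail t. The direction of the
#' frequency difference is reported per TE. TEs on arms without SNP
#' thresholds are skipped with a warning.
#'
#' @param scored output of [te_fst()].
#' @param thresholds the `thresholds` data.frame from [arm_thresholds()]
#'   run on the SNP scan.
#' @param tails tail sizes to call at.
#' @return `scored` (testable TEs only) with a logical column per tail
#'   (`cand_top5`, ...) and `direction` (which population is higher).
#' @export
te_candidates <- function(scored, thresholds, tails = c(0.05, 0.01, 0.005)) {
  t_ok <- scored$classification == "testable" & !is.na(scored$theta)
  out <- scored[t_ok, , drop = FALSE]
  no_thr <- setdiff(unique(out$arm), unique(thresholds$arm))
  if (length(no_thr)) {
    warning("no SNP threshold for arm(s) ", paste(no_thr, collapse = ", "),
            "; TEs there skipped")
    out <- out[!out$arm %in% no_thr, , drop = FALSE]
  }
  for (t in sort(tails, decreasing = TRUE)) {
    crit <- thresholds$critical[thresholds$tail == t]
    names(crit) <- thresholds$arm[thresholds$tail == t]
    out[[paste0("cand_", tier_label(t))]] <- out$theta >= crit[out$arm]
  }
  fcols <- grep("^freq_", names(out), value = TRUE)[1:2]
  pops <- sub("^freq_", "", fcols)
  out$direction <- ifelse(
    out[[fcols[1]]] == out[[fcols[2]]], "equal",
    ifelse(out[[fcols[1]]] > out[[fcols[2]]],
           paste(pops[1], ">", pops[2]), paste(pops[2], ">", pops[1])))
  rownames(out) <- NULL
  out
}
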