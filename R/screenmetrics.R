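# Hit-list construction and screening-power metrics. Scores are rankings:
# lower = better throughout. Molecules whose every state failed the backend
# are excluded from both the numerator and the totals.

#' Build a per-molecule hit list from score records
#'
#' Drops failed records, collapses multiple states (protonation/chirality
#' variants) of one parent molecule to the lowest surviving score, and sorts
#' ascending (best first) with ties broken by parent id lexicographically so
#' the ordering is stable across runs.
#'
#' @param records data.frame of score records for a single variant, with
#'   columns `parent_id`, `qmds` (or `score`), `status`, `is_ligand`
#' @return a `hitlist`: list with `table` (data.frame parent_id, score,
#'   is_ligand in rank order), `hits_total`, `n_total`, `excluded`
#'   (parent ids dropped because all their states failed)
#' @export
build_hitlist <- function(records) {
  score_col <- if ("qmds" %in% names(records)) "qmds" else "score"
  stopifnot(all(c("parent_id", "is_ligand") %in% names(records)))
  if (length(unique(records$variant)) > 1L)
    stop("records mix score variants; filter to one variant first")
  status <- records$status %||% rep("converged", nrow(records))
  ok <- status == "converged" & is.finite(records[[score_col]])
  if (!any(ok)) stop("all score records failed; nothing to rank")
  excluded <- setdiff(unique(records$parent_id),
                      unique(records$parent_id[ok]))
  recs <- records[ok, , drop = FALSE]
  agg <- stats::aggregate(recs[[score_col]],
                          by = list(parent_id = recs$parent_id), FUN = min)
  names(agg)[2L] <- "score"
  lab <- recs$is_ligand[match(agg$parent_id, recs$parent_id)]
  tab <- data.frame(parent_id = agg$parent_id, score = agg$score,
                    is_ligand = lab, stringsAsFactors = FALSE)
  tab <- tab[order(tab$score, tab$parent_id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 hits_total = sum(tab$is_ligand),
                 n_total = nrow(tab),
                 excluded = excluded),
            class = "hitlist")
}

#' @export
print.hitlist <- function(x, ...) {
  cat(sprintf("<hitlist> %d molecules (%d ligands), %d excluded by QM failure\n",
              x$n_total, x$hits_total, length(x$excluded)))
  invisible(x)
}

#' Enrichment factor at a database percentage
#'
#' \deqn{EF(x) = \frac{Hits_{x\%} / N_{x\%}}{Hits_{total} / N_{total}}}
#' the ligand fraction among the top x% of the ranked list relative to the
#' ligand fraction overall. The top-set size is
#' \eqn{N_{x\%} = \lceil x N_{total} / 100 \rceil} (ceiling, so the set is
#' never empty for x > 0); EF(100) = 1 identically.
#'
#' @param hitlist a `hitlist`
#' @param x percentage of the screened database, in (0, 100]
#' @return EF(x) (numeric)
#' @export
enrichment_factor <- function(hitlist, x) {
  stopifnot(inherits(hitlist, "hitlist"), x > 0, x <= 100)
  if (hitlist$hits_total < 1L)
    stop("EF undefined: hit list contains no ligands")
  n_x <- ceiling(x * hitlist$n_total / 100)
  hits_x <- sum(hitlist$table$is_ligand[seq_len(n_x)])
  (hits_x / n_x) / (hitlist$hits_total / hitlist$n_total)
}

#' ROC curve and AUC of a hit list
#'
#' Sweeps the score threshold over the ranked list and integrates the curve
#' by the trapezoid rule, which credits tied ligand-decoy pairs 0.5 -- the
#' result is exactly the Mann-Whitney pair-counting statistic.
#'
#' @param hitlist a `hitlist` with both ligands and decoys present
#' @return list with `roc` (data.frame `fpr`, `tpr`, starting at (0,0) and
#'   ending at (1,1)) and `auc`
#' @export
roc_auc <- function(hitlist) {
  tab <- hitlist$table
  pos <- sum(tab$is_ligand); neg <- sum(!tab$is_ligand)
  if (pos == 0L || neg == 0L)
    stop("ROC needs both ligands and decoys in the hit list")
  # advance through blocks of tied scores
  blocks <- split(seq_len(nrow(tab)), match(tab$score, unique(tab$score)))
  tpr <- c(0, cumsum(vapply(blocks, function(ix) sum(tab$is_ligand[ix]), 0)) / pos)
  fpr <- c(0, cumsum(vapply(blocks, function(ix) sum(!tab$is_ligand[ix]), 0)) / neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Enrichment-plot curve
#'
#' Percentage of true ligands recovered as a function of the percentage of
#' the ranked database screened: a monotone nondecreasing step curve from
#' (0, 0) to (100, 100). Random ranking tracks the diagonal; perfect ranking
#' recovers all ligands once Hits_total/N_total of the database is screened.
#'
#' @param hitlist a `hitlist`
#' @return data.frame with `pct_screened`, `pct_ligands_found`
#' @export
enrichment_plot_data <- function(hitlist) {
  tab <- hitlist$table
  n <- nrow(tab)
  data.frame(pct_screened = c(0, 100 * seq_len(n) / n),
             pct_ligands_found = c(0, 100 * cumsum(tab$is_ligand) /
                                     hitlist$hits_total))
}

#' Summarize screening power of a score table
#'
#' @param records score records (one variant) or a prebuilt `hitlist`
#' @param ef_percent EF thresholds to report (default 1, 2, 5, 10; the 1 and
#'   2 percent values are the early-enrichment headline numbers)
#' @return data.frame with one row: EF at each threshold, AUC, totals
#' @export
screening_summary <- function(records, ef_percent = c(1, 2, 5, 10)) {
  hl <- if (inherits(records, "hitlist")) records else build_hitlist(records)
  efs <- vapply(ef_percent, function(x) enrichment_factor(hl, x), 0)
  out <- as.data.frame(as.list(stats::setNames(
    efs, paste0("EF", ef_percent))))
  out$AUC <- roc_auc(hl)$auc
  out$n_total <- hl$n_total
  out$hits_total <- hl$hits_total
  out$n_excluded <- length(hl$excluded)
  out
}
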