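score_param_names <- function() {
  c("interface_score", "interface_area", "dg_bind", "hbond_energy")
}

#' Normalize the four scoring parameters to \[0, 1\]
#'
#' Per parameter, an affine map onto \[0, 1\] oriented so that 1 is better:
#' for the three energy terms the lowest value maps to 1, for the interface
#' area the largest maps to 1. A parameter that is constant across the
#' population maps to 0.5 everywhere.
#'
#' @param records score data.frame from [score_poses()] (>= 2 rows)
#' @return the records with added `norm_*` columns
#' @export
normalize_scores <- function(records) {
  if (nrow(records) < 2L) stop("need at least 2 records to normalize")
  higher_better <- c(interface_score = FALSE, interface_area = TRUE,
                     dg_bind = FALSE, hbond_energy = FALSE)
  for (p in score_param_names()) {
    v <- records[[p]]
    rng <- range(v)
    if (diff(rng) == 0) {
      records[[paste0("norm_", p)]] <- rep(0.5, length(v))
    } else {
      n <- (v - rng[1]) / diff(rng)
      records[[paste0("norm_", p)]] <- if (higher_better[[p]]) n else 1 - n
    }
  }
  records
}

rank_classes <- function(score, labels) {
  ord <- order(-score, labels)
  rank <- integer(length(score))
  rank[ord] <- seq_along(score)
  rank
}

#' Consensus ranking of interface classes by value averaging
#'
#' For each scoring parameter, the `top_n` best dimers by the normalized
#' parameter are taken and each class receives the mean normalized value
#' over its members in that subset (0 when absent). The combined consensus
#' uses the unweighted mean of the four normalized parameters: the `top_n`
#' dimers by that combined score are taken and classes are ranked by their
#' per-class mean combined score, descending. `per_class_top = TRUE`
#' switches to the alternative reading in which each class averages its own
#' `top_n` best members over the whole population.
#'
#' @param records normalized, class-labeled score data.frame
#'   (see [normalize_scores()])
#' @param top_n population cutoff (default 100)
#' @param per_class_top use per-class top members instead of the global
#'   top-`top_n` subset
#' @return object of class `ConsensusResult` with per-parameter and combined
#'   class scores and ranks
#' @export
consensus_by_values <- function(records, top_n = 100L, per_class_top = FALSE) {
  if (top_n < 1) stop("top_n must be >= 1")
  stopifnot(all(paste0("norm_", score_param_names()) %in% names(records)))
  classes <- sort(unique(records$class))
  per_param <- list()
  class_mean <- function(v, cls) {
    out <- setNames(rep(0, length(classes)), classes)
    m <- tapply(v, cls, mean)
    out[names(m)] <- m
    out
  }
  for (p in score_param_names()) {
    v <- records[[paste0("norm_", p)]]
    if (per_class_top) {
      sc <- setNames(rep(0, length(classes)), classes)
      for (cl in classes) {
        vc <- sort(v[records$class == cl], decreasing = TRUE)
        sc[cl] <- mean(head(vc, top_n))
      }
      per_param[[p]] <- sc
    } else {
      keep <- order(-v)[seq_len(min(top_n, length(v)))]
      per_param[[p]] <- class_mean(v[keep], records$class[keep])
    }
  }
  combined_member <- rowMeans(
    sapply(score_param_names(), function(p) records[[paste0("norm_", p)]]))
  if (per_class_top) {
    comb <- setNames(rep(0, length(classes)), classes)
    for (cl in classes) {
      vc <- sort(combined_member[records$class == cl], decreasing = TRUE)
      comb[cl] <- mean(head(vc, top_n))
    }
  } else {
    keep <- order(-combined_member)[seq_len(min(top_n, length(combined_member)))]
    comb <- class_mean(combined_member[keep], records$class[keep])
  }
  res <- list(method = "values", classes = classes,
              per_param = per_param, combined = comb,
              rank = rank_classes(comb, classes), top_n = as.integer(top_n),
              per_class_top = per_class_top)
  class(res) <- "ConsensusResult"
  res
}

#' Consensus ranking of interface classes by top-population frequency
#'
#' For each scoring parameter, the frequency of each class among the `top_n`
#' best dimers by that (normalized) parameter; frequencies over classes sum
#' to one per parameter. The combined consensus is the mean of the four
#' per-parameter frequencies; ties are broken by the combined
#' value-consensus score, then by label order.
#'
#' @inheritParams consensus_by_values
#' @return object of class `ConsensusResult`
#' @export
consensus_by_frequency <- function(records, top_n = 100L) {
  if (top_n < 1) stop("top_n must be >= 1")
  stopifnot(all(paste0("norm_", score_param_names()) %in% names(records)))
  classes <- sort(unique(records$class))
  per_param <- list()
  counts <- matrix(0L, length(classes), length(score_param_names()),
                   dimnames = list(classes, score_param_names()))
  for (p in score_param_names()) {
    v <- records[[paste0("norm_", p)]]
    keep <- order(-v)[seq_len(min(top_n, length(v)))]
    tab <- table(factor(records$class[keep], levels = classes))
    counts[, p] <- as.integer(tab)
    per_param[[p]] <- setNames(as.numeric(tab) / length(keep), classes)
  }
  comb <- rowMeans(do.call(cbind, per_param))
  vals <- consensus_by_values(records, top_n = top_n)
  # rank on the exact integer membership counts so equal frequencies tie
  # exactly and fall through to the value-consensus tie-break
  ord <- order(-rowSums(counts), -vals$combined[classes], classes)
  rank <- integer(length(classes)); rank[ord] <- seq_along(classes)
  res <- list(method = "frequency", classes = classes,
              per_param = per_param, combined = comb, rank = rank,
              top_n = as.integer(top_n), value_combined = vals$combined)
  class(res) <- "ConsensusResult"
  res
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat("ConsensusResult (", x$method, " method, top ", x$top_n, ")\n", sep = "")
  best <- x$classes[order(x$rank)]
  cat("  top classes:", paste(head(best, 5), collapse = " "), "\n")
  invisible(x)
}

#' Top-ranked interface classes per parameter and method
#'
#' Emits, per scoring parameter and for the combined consensus, the top-`k`
#' class labels in descending order — the layout of a best-scored-interfaces
#' summary table. When `k` exceeds the class count all classes are listed.
#'
#' @param result a `ConsensusResult`
#' @param k number of labels per row
#' @param path optional TSV output path
#' @return data.frame with a `scoring_parameter` column and `rank1..rankk`
#'   columns
#' @export
rank_report <- function(result, k = 3L, path = NULL) {
  stopifnot(inherits(result, "ConsensusResult"))
  kk <- min(k, length(result$classes))
  top_of <- function(score) {
    lbl <- result$classes[order(-score, result$classes)]
    head(lbl, kk)
  }
  rows <- lapply(score_param_names(), function(p) top_of(result$per_param[[p]]))
  rows[[length(rows) + 1]] <- result$classes[order(result$rank)][seq_len(kk)]
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- paste0("rank", seq_len(kk))
  out <- cbind(scoring_parameter = c(score_param_names(),
                                     paste0("consensus_", result$method)),
               out, stringsAsFactors = FALSE)
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
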