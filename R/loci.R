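#' Approximate Bayes factor credible sets (single causal variant)
#'
#' Wakefield approximate Bayes factors per variant,
#' `ABF = sqrt(se^2 / (se^2 + W)) * exp(z^2 W / (2 (se^2 + W)))` with prior
#' effect variance `W = prior_sd^2`; under the single-causal-variant model
#' the posterior inclusion probabilities are the normalised ABFs and the
#' credible set is the smallest pip-ranked set reaching the coverage target.
#' A region with no genome-wide significant variant yields no set; on
#' numerical failure a fallback single-variant set (most significant
#' variant) is returned with `fallback_flag = TRUE`.
#'
#' Top-variant tie-breaks: highest pip, then lowest p, then smallest
#' position (for determinism).
#'
#' @param region sumstats slice for one region (within one LD block).
#' @param prior_sd prior SD of the effect (default 0.2, a standard log-odds
#'   scale prior for binary traits).
#' @param coverage target posterior coverage (default 0.95).
#' @param gw_threshold significance gate for emitting a set (default 5e-8).
#' @return list of credible sets (here 0 or 1): each a list with `members`
#'   (data.frame `variant_id`, `pip`, ordered), `top_variant`, `coverage`,
#'   `fallback_flag`.
#' @export
abf_credible_sets <- function(region, prior_sd = 0.2, coverage = 0.95,
                              gw_threshold = 5e-8) {
  if (nrow(region) == 0) {
    message("abf_credible_sets: empty region, no sets")
    return(list())
  }
  if (!any(region$p < gw_threshold)) return(list())
  W <- prior_sd^2
  v <- region$se^2
  log_abf <- 0.5 * log(v / (v + W)) + region$z^2 / 2 * W / (v + W)
  if (any(!is.finite(log_abf))) {
    i <- which.min(region$p)
    return(list(list(
      members = data.frame(variant_id = region$variant_id[i], pip = 1,
                           stringsAsFactors = FALSE),
      top_variant = region$variant_id[i], coverage = coverage,
      fallback_flag = TRUE)))
  }
  pip <- exp(log_abf - max(log_abf))
  pip <- pip / sum(pip)
  ord <- order(-pip, region$p, region$pos)
  csum <- cumsum(pip[ord])
  n_in <- which(csum >= coverage)[1]
  members <- data.frame(variant_id = region$variant_id[ord][seq_len(n_in)],
                        pip = pip[ord][seq_len(n_in)],
                        stringsAsFactors = FALSE)
  list(list(members = members, top_variant = members$variant_id[1],
            coverage = coverage, fallback_flag = FALSE,
            pip_all = stats::setNames(pip, region$variant_id)))
}

#' Define non-overlapping loci by merging nearby index variants
#'
#' Single-linkage (transitive) merging of index variants within
#' `merge_distance` of one another on the same chromosome; locus bounds are
#' the min/max member positions, ids `chrom:start-end` are assigned in
#' genomic order. Deterministic and invariant under input permutation.
#'
#' @param index_variants data.frame with columns `chrom`, `pos`, `study`,
#'   `p` (and optionally `variant_id`).
#' @param merge_distance merging distance in base pairs (default 1e6).
#' @return a `locus_catalogue` data.frame: `locus_id`, `chrom`, `start`,
#'   `end`, `n_index`, `source_studies` (comma-joined), `top_p`.
#' @export
define_loci <- function(index_variants, merge_distance = 1e6) {
  iv <- as.data.frame(index_variants)
  if (nrow(iv) == 0) {
    out <- data.frame(locus_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_index = integer(0), source_studies = character(0),
                      top_p = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("locus_catalogue", "data.frame")
    return(out)
  }
  if (!"study" %in% names(iv)) iv$study <- "study"
  if (!"p" %in% names(iv)) iv$p <- NA_real_
  iv$chrom <- as.character(iv$chrom)
  iv <- iv[order(chrom_rank(iv$chrom), iv$pos), , drop = FALSE]
  new_locus <- c(TRUE, iv$chrom[-1] != iv$chrom[-nrow(iv)] |
                   diff(iv$pos) > merge_distance)
  grp <- cumsum(new_locus)
  rows <- lapply(split(iv, grp), function(g) {
    data.frame(chrom = g$chrom[1], start = min(g$pos), end = max(g$pos),
               n_index = nrow(g),
               source_studies = paste(sort(unique(g$study)), collapse = ","),
               top_p = suppressWarnings(min(g$p, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
  out$locus_id <- paste0(out$chrom, ":", out$start, "-", out$end)
  out$top_p[!is.finite(out$top_p)] <- NA_real_
  rownames(out) <- NULL
  out <- out[, c("locus_id", "chrom", "start", "end", "n_index",
                 "source_studies", "top_p")]
  class(out) <- c("locus_catalogue", "data.frame")
  out
}

chrom_rank <- function(chrom) {
  suppressWarnings(num <- as.numeric(chrom))
  ifelse(is.na(num), 100 + as.integer(factor(chrom)), num)
}

#' Consolidate per-study locus catalogues with novelty flags
#'
#' Re-merges loci across studies with the same distance rule (applied to
#' locus midpoint representatives via their member bounds: two loci merge
#' when their intervals are within `merge_distance`). Each consolidated
#' locus carries the union of source studies; `novel_flag` is TRUE iff no
#' reference study contributed.
#'
#' @param catalogues named list of `locus_catalogue`s (names = study labels;
#'   falls back to each catalogue's `source_studies`).
#' @param reference_studies character vector of study labels considered
#'   previously known.
#' @param merge_distance merging distance (default 1e6).
#' @return `locus_catalogue` with extra column `novel_flag`.
#' @export
consolidate_loci <- function(catalogues, reference_studies,
                             merge_distance = 1e6) {
  pieces <- lapply(seq_along(catalogues), function(i) {
    cat_i <- catalogues[[i]]
    lab <- names(catalogues)[i] %||% unique(cat_i$source_studies)
    if (nrow(cat_i) == 0) return(NULL)
    data.frame(chrom = cat_i$chrom, start = cat_i$start, end = cat_i$end,
               study = lab, top_p = cat_i$top_p, stringsAsFactors = FALSE)
  })
  all_loci <- do.call(rbind, pieces)
  if (is.null(all_loci) || nrow(all_loci) == 0) {
    return(define_loci(data.frame()))
  }
  ids <- unlist(lapply(catalogues, function(cat_i) {
    stats::setNames(cat_i$chrom, cat_i$locus_id)
  }))
  if (length(ids) > 0 &&
      any(tapply(ids, names(ids), function(v) length(unique(v))) > 1)) {
    stop("conflicting chromosome labels for a shared locus id")
  }
  all_loci <- all_loci[order(chrom_rank(all_loci$chrom), all_loci$start), ]
  n <- nrow(all_loci)
  new_locus <- c(TRUE, all_loci$chrom[-1] != all_loci$chrom[-n] |
                   (all_loci$start[-1] -
                      cummax_by(all_loci$end, all_loci$chrom)[-n]) >
                   merge_distance)
  grp <- cumsum(new_locus)
  rows <- lapply(split(all_loci, grp), function(g) {
    data.frame(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
               n_index = nrow(g),
               source_studies = paste(sort(unique(g$study)), collapse = ","),
               top_p = suppressWarnings(min(g$top_p, na.rm = TRUE)),
               novel_flag = !any(g$study %in% reference_studies),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
  out$locus_id <- paste0(out$chrom, ":", out$start, "-", out$end)
  out$top_p[!is.finite(out$top_p)] <- NA_real_
  rownames(out) <- NULL
  out <- out[, c("locus_id", "chrom", "start", "end", "n_index",
                 "source_studies", "novel_flag", "top_p")]
  class(out) <- c("locus_catalogue", "data.frame")
  out
}

## running per-chromosome cumulative max (for interval merging)
cummax_by <- function(x, g) {
  out <- numeric(length(x))
  for (gg in unique(g)) {
    i <- g == gg
    out[i] <- cummax(x[i])
  }
  out
}

#' Aggregate gene nominations into per-locus gene scores
#'
#' Each (locus, study, method) nomination contributes 0.5 points to its
#' gene; scores are summed per gene per locus across studies and methods.
#' The maximal-score gene(s) lead; when several genes tie, or the gap
#' between the top two scores is below `tie_margin` (default 1.0), all such
#' genes are retained as joint candidates.
#'
#' @param nominations data.frame with columns `locus_id`, `study`, `method`,
#'   `gene`. (locus, study, method) must be unique.
#' @param tie_margin minimum top-two gap for a sole lead (default 1.0).
#' @param known_loci optional character vector of valid locus ids; unknown
#'   ids raise an error listing the offenders.
#' @return list with `scores` (data.frame `locus_id`, `gene`, `score`,
#'   `lead`) and `leads` (data.frame `locus_id`, `lead_genes`
#'   comma-joined, `top_score`).
#' @export
score_genes <- function(nominations, tie_margin = 1.0, known_loci = NULL) {
  nm <- as.data.frame(nominations)
  stopifnot(all(c("locus_id", "study", "method", "gene") %in% names(nm)))
  if (!is.null(known_loci)) {
    bad <- setdiff(unique(nm$locus_id), known_loci)
    if (length(bad) > 0) {
      stop("nominations reference unknown locus id(s): ",
           paste(bad, collapse = ", "))
    }
  }
  key <- paste(nm$locus_id, nm$study, nm$method)
  if (anyDuplicated(key)) stop("duplicate (locus, study, method) nomination")

  agg <- stats::aggregate(list(score = rep(0.5, nrow(nm))),
                          by = list(locus_id = nm$locus_id, gene = nm$gene),
                          FUN = sum)
  agg <- agg[order(agg$locus_id, -agg$score, agg$gene), ]
  rownames(agg) <- NULL

  leads <- lapply(split(agg, agg$locus_id), function(g) {
    top <- max(g$score)
    second <- if (nrow(g) > 1) sort(g$score, decreasing = TRUE)[2] else -Inf
    lead_genes <- g$gene[g$score == top]
    if (nrow(g) > 1 && (top - second) < tie_margin) {
      lead_genes <- g$gene[g$score >= second]
    }
    data.frame(locus_id = g$locus_id[1],
               lead_genes = paste(sort(lead_genes), collapse = ","),
               top_score = top, stringsAsFactors = FALSE)
  })
  leads <- do.call(rbind, leads)
  rownames(leads) <- NULL
  agg$lead <- mapply(function(l, g) {
    g %in% strsplit(leads$lead_genes[leads$locus_id == l], ",")[[1]]
  }, agg$locus_id, agg$gene)
  list(scores = agg, leads = leads)
}
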