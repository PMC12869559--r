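#' Construct and validate a summary-statistics table
#'
#' A `sumstats` object is a `data.frame` with one row per variant and the
#' canonical columns `variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `z`, `p` and (optionally) `n_case`,
#' `n_control`, `n`, `n_eff`. It is the lingua franca of every downstream
#' stage. Missing statistics are reconstructed where possible:
#' `z = beta / se`, `p = 2 * pnorm(-|z|)`, and from a p-value alone
#' `z = sign(beta) * qnorm(1 - p / 2)`. When both `z` and `beta / se` are
#' present but disagree by more than `z_tol` (relative), `z` wins and `p` is
#' recomputed from it.
#'
#' Rows violating the invariants (`se > 0`, `0 < eaf < 1`, `p` in (0, 1],
#' non-finite effect fields, duplicated `variant_id`) are dropped with a
#' message reporting counts.
#'
#' @param df data.frame with at least `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf` and one of (`beta` + `se`), (`z`), (`beta` + `p`).
#' @param trait_label character scalar naming the trait.
#' @param z_tol relative tolerance for the `z` versus `beta/se` consistency
#'   check.
#' @return A `sumstats` object (data.frame), with attributes `trait_label`
#'   and `n_dropped`.
#' @export
as_sumstats <- function(df, trait_label = "trait", z_tol = 1e-3) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  mandatory <- c("chrom", "pos", "effect_allele", "other_allele", "eaf")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!any(c("beta", "z") %in% names(df))) {
    stop("missing mandatory column(s): need 'beta' or 'z'")
  }
  if (!any(c("se", "p") %in% names(df))) {
    stop("missing mandatory column(s): need 'se' or 'p'")
  }

  df$chrom <- as.character(df$chrom)
  for (col in intersect(c("pos", "eaf", "beta", "se", "z", "p",
                          "n_case", "n_control", "n"), names(df))) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))

  n_in <- nrow(df)

  ## reconstruct the statistic triplet
  if (!"z" %in% names(df)) df$z <- NA_real_
  if (!"beta" %in% names(df)) df$beta <- NA_real_
  if (!"se" %in% names(df)) df$se <- NA_real_
  if (!"p" %in% names(df)) df$p <- NA_real_

  i <- is.na(df$z) & !is.na(df$beta) & !is.na(df$se) & df$se > 0
  df$z[i] <- df$beta[i] / df$se[i]
  i <- is.na(df$z) & !is.na(df$p) & !is.na(df$beta)
  df$z[i] <- sign(df$beta[i]) * stats::qnorm(1 - df$p[i] / 2)
  ## z wins over an inconsistent beta/se or p
  zb <- !is.na(df$z) & !is.na(df$beta) & !is.na(df$se) & df$se > 0
  incons <- zb & abs(df$z - df$beta / df$se) > z_tol * pmax(abs(df$z), 1e-12)
  zp <- !is.na(df$z) & !is.na(df$p)
  p_from_z <- 2 * stats::pnorm(-abs(df$z))
  incons_p <- zp & abs(df$p - p_from_z) > z_tol * pmax(p_from_z, 1e-300)
  if (any(incons | incons_p, na.rm = TRUE)) {
    message(sum(incons | incons_p, na.rm = TRUE),
            " variant(s) with statistics inconsistent with z; z retained")
  }
  df$beta[is.na(df$beta)] <- (df$z * df$se)[is.na(df$beta)]
  i <- is.na(df$se) & !is.na(df$beta) & !is.na(df$z) & df$z != 0
  df$se[i] <- abs(df$beta[i] / df$z[i])
  df$p <- 2 * stats::pnorm(-abs(df$z))
  df$p[df$p == 0] <- .Machine$double.xmin

  if (!"variant_id" %in% names(df) || all(is.na(df$variant_id))) {
    df$variant_id <- variant_key(df$chrom, df$pos, df$effect_allele, df$other_allele)
  }
  df$variant_id <- as.character(df$variant_id)

  if (all(c("n_case", "n_control") %in% names(df))) {
    df$n_eff <- 4 / (1 / df$n_case + 1 / df$n_control)
  }

  ok <- !is.na(df$pos) & !is.na(df$z) & !is.na(df$se) & df$se > 0 &
    !is.na(df$eaf) & df$eaf > 0 & df$eaf < 1 &
    !is.na(df$p) & df$p > 0 & df$p <= 1 & is.finite(df$beta)
  ok[is.na(ok)] <- FALSE
  df <- df[ok, , drop = FALSE]
  dup <- duplicated(df$variant_id)
  if (any(dup)) df <- df[!dup, , drop = FALSE]

  n_dropped <- n_in - nrow(df)
  if (n_dropped > 0) {
    message("dropped ", n_dropped, " of ", n_in,
            " row(s) failing validation for trait '", trait_label, "'")
  }

  front <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
             "eaf", "beta", "se", "z", "p")
  df <- df[, c(front, setdiff(names(df), front)), drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("sumstats", "data.frame"),
            trait_label = trait_label, n_dropped = n_dropped)
}

#' Trait label of a sumstats table
#' @param x sumstats object.
#' @return character scalar.
#' @export
trait_label <- function(x) attr(x, "trait_label") %||% "trait"

`%||%` <- function(a, b) if (is.null(a)) b else a

## (chrom, pos, unordered allele pair) join key; rsIDs are carried, never joined on
variant_key <- function(chrom, pos, a1, a2) {
  paste(chrom, format(pos, scientific = FALSE, trim = TRUE),
        pmin(a1, a2), pmax(a1, a2), sep = ":")
}

is_ambiguous <- function(a1, a2) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(comp[a1]) & comp[a1] == a2
}

#' Read a summary-statistics file
#'
#' Reads a tab-delimited (optionally gzipped) file into a validated
#' [as_sumstats()] table. Foreign column names are supported through
#' `dialect`, a named character vector mapping canonical names to the file's
#' header names, e.g. `c(chrom = "CHR", pos = "BP", beta = "B")`; canonical
#' names absent from the mapping are looked up verbatim.
#'
#' @param path file path.
#' @param dialect named character vector (canonical -> file column name),
#'   or NULL for canonical headers.
#' @param trait_label trait name stored on the result.
#' @param ... passed to [as_sumstats()].
#' @return A `sumstats` object.
#' @export
read_sumstats <- function(path, dialect = NULL, trait_label = "trait", ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      file_col <- dialect[[canon]]
      if (!file_col %in% names(raw)) {
        stop("column-mapping names '", file_col, "' for '", canon,
             "' but the file has no such column")
      }
      names(raw)[names(raw) == file_col] <- canon
    }
  }
  as_sumstats(raw, trait_label = trait_label, ...)
}

#' Write a summary-statistics table in the canonical dialect
#'
#' Tab-separated with canonical headers; `.gz` paths are compressed.
#'
#' @param x sumstats object.
#' @param path output path.
#' @export
write_sumstats <- function(x, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Harmonise a pair of summary-statistics tables
#'
#' Intersects two tables on the shared (chrom, pos, unordered allele pair)
#' key. Where the effect alleles differ, the second table's `beta`, `z` are
#' negated and `eaf` complemented so that both tables report effects for the
#' same allele. Strand-ambiguous variants (A/T, C/G) are removed when
#' `remove_ambiguous` is TRUE. Output row order is identical across the pair
#' (genomic order of the first table).
#'
#' @param a,b sumstats objects.
#' @param remove_ambiguous drop strand-ambiguous variants.
#' @return list with elements `a` and `b`, harmonised and equally ordered.
#' @export
harmonize_pair <- function(a, b, remove_ambiguous = FALSE) {
  key_a <- variant_key(a$chrom, a$pos, a$effect_allele, a$other_allele)
  key_b <- variant_key(b$chrom, b$pos, b$effect_allele, b$other_allele)
  idx_b <- match(key_a, key_b)
  keep <- !is.na(idx_b)
  if (remove_ambiguous) {
    keep <- keep & !is_ambiguous(a$effect_allele, a$other_allele)
  }
  if (!any(keep)) stop("harmonize_pair: empty variant intersection")
  a2 <- a[keep, , drop = FALSE]
  b2 <- b[idx_b[keep], , drop = FALSE]

  ord <- order(a2$chrom, a2$pos)
  a2 <- a2[ord, , drop = FALSE]
  b2 <- b2[ord, , drop = FALSE]

  flip <- b2$effect_allele != a2$effect_allele
  if (any(flip)) {
    b2$beta[flip] <- -b2$beta[flip]
    b2$z[flip] <- -b2$z[flip]
    b2$eaf[flip] <- 1 - b2$eaf[flip]
    tmp <- b2$effect_allele[flip]
    b2$effect_allele[flip] <- b2$other_allele[flip]
    b2$other_allele[flip] <- tmp
  }
  rownames(a2) <- rownames(b2) <- NULL
  list(a = restore_sumstats(a2, a), b = restore_sumstats(b2, b))
}

restore_sumstats <- function(df, template) {
  structure(df, class = c("sumstats", "data.frame"),
            trait_label = trait_label(template))
}

#' Quality-control configuration
#'
#' @param min_fraction_n retain variants with sample size at least this
#'   fraction of the table maximum (in (0, 1]); NULL disables the filter.
#' @param n_mode which sample size the fraction applies to: the effective
#'   size `n_eff` or the total `n`.
#' @param excluded_regions data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive); variants inside any region are removed.
#' @param min_eaf retain variants with `eaf` in `[min_eaf, 1 - min_eaf]`.
#' @param remove_ambiguous drop strand-ambiguous (A/T, C/G) variants.
#' @return a `qc_config` list.
#' @export
qc_config <- function(min_fraction_n = NULL, n_mode = c("effective", "total"),
                      excluded_regions = NULL, min_eaf = 0,
                      remove_ambiguous = FALSE) {
  n_mode <- match.arg(n_mode)
  if (!is.null(min_fraction_n) &&
      (min_fraction_n <= 0 || min_fraction_n > 1)) {
    stop("min_fraction_n must lie in (0, 1]")
  }
  if (!is.null(excluded_regions)) {
    excluded_regions <- as.data.frame(excluded_regions)
    stopifnot(all(c("chrom", "start", "end") %in% names(excluded_regions)))
    if (any(excluded_regions$start > excluded_regions$end)) {
      stop("excluded_regions must have start <= end")
    }
  }
  structure(list(min_fraction_n = min_fraction_n, n_mode = n_mode,
                 excluded_regions = excluded_regions, min_eaf = min_eaf,
                 remove_ambiguous = remove_ambiguous),
            class = "qc_config")
}

#' Apply quality-control filters to a summary-statistics table
#'
#' Retains variants with (i) sample size at least `min_fraction_n` times the
#' table maximum (effective or total per `n_mode`), (ii) positions outside
#' all excluded regions (1-based inclusive), (iii) `eaf` within
#' `[min_eaf, 1 - min_eaf]`, and (iv, optionally) unambiguous strand. The
#' per-filter removal counts are attached as attribute `qc_report` and
#' reported via `message()`.
#'
#' @param t sumstats object.
#' @param cfg a [qc_config()].
#' @return filtered `sumstats` object.
#' @export
apply_qc <- function(t, cfg) {
  stopifnot(inherits(cfg, "qc_config"))
  keep <- rep(TRUE, nrow(t))
  report <- c()

  if (!is.null(cfg$min_fraction_n)) {
    nvec <- if (cfg$n_mode == "effective") t$n_eff else t$n
    if (is.null(nvec) || all(is.na(nvec))) {
      stop("min_fraction_n set but the table lacks ",
           if (cfg$n_mode == "effective") "n_eff" else "n")
    }
    pass <- !is.na(nvec) & nvec >= cfg$min_fraction_n * max(nvec, na.rm = TRUE)
    report["sample_size"] <- sum(keep & !pass)
    keep <- keep & pass
  }
  if (!is.null(cfg$excluded_regions)) {
    inside <- rep(FALSE, nrow(t))
    for (r in seq_len(nrow(cfg$excluded_regions))) {
      reg <- cfg$excluded_regions[r, ]
      inside <- inside | (t$chrom == as.character(reg$chrom) &
                            t$pos >= reg$start & t$pos <= reg$end)
    }
    report["excluded_region"] <- sum(keep & inside)
    keep <- keep & !inside
  }
  if (cfg$min_eaf > 0) {
    pass <- t$eaf >= cfg$min_eaf & t$eaf <= 1 - cfg$min_eaf
    report["eaf"] <- sum(keep & !pass)
    keep <- keep & pass
  }
  if (cfg$remove_ambiguous) {
    pass <- !is_ambiguous(t$effect_allele, t$other_allele)
    report["ambiguous"] <- sum(keep & !pass)
    keep <- keep & pass
  }
  out <- t[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (length(report) > 0 && sum(report) > 0) {
    message("apply_qc removed ", sum(report), " variant(s): ",
            paste(names(report), report, sep = "=", collapse = ", "))
  }
  out <- restore_sumstats(out, t)
  attr(out, "qc_report") <- report
  out
}
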