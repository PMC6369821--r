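#' Replicate z-scores of editing levels
#'
#' For each site, standardises every replicate's editing level against the
#' grand mean and standard deviation computed over ALL covered replicates of
#' ALL populations at that site. A replicate far in the tail (|z| > 1.65,
#' roughly the one-sided 5% point of the normal) indicates a population whose
#' editing departs from the ensemble.
#'
#' @param cm `edit_counts` at replicate resolution.
#' @param sheet `sample_sheet`.
#' @param min_coverage a replicate enters the ensemble at a site only with at
#'   least this many reads there (default 1: any defined level).
#' @param sd_type "sample" (n - 1 denominator, default) or "population" (n).
#' @return data.frame: site_id, chrom, pos, strand, sample_id, population,
#'   replicate, level, z. Sites with fewer than 2 covered replicates or zero
#'   level variance are omitted (their z is undefined).
#' @export
replicate_zscores <- function(cm, sheet, min_coverage = 1,
                              sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  lv <- editing_levels(cm)
  tot <- cm$a + cm$g
  idx <- match(cm$samples, sheet$sample_id)
  if (anyNA(idx))
    stop("samples missing from the sample sheet: ",
         paste(cm$samples[is.na(idx)], collapse = ", "))
  rows <- vector("list", nrow(cm$sites))
  for (i in seq_len(nrow(cm$sites))) {
    cov <- which(tot[i, ] >= min_coverage & !is.na(lv[i, ]))
    if (length(cov) < 2) next
    v <- lv[i, cov]
    mu <- mean(v)
    sdv <- if (sd_type == "sample") stats::sd(v)
      else sqrt(mean((v - mu)^2))
    if (!is.finite(sdv) || sdv == 0) next
    rows[[i]] <- data.frame(
      site_id = site_id(cm$sites[i, , drop = FALSE]),
      chrom = cm$sites$chrom[i], pos = cm$sites$pos[i],
      strand = cm$sites$strand[i],
      sample_id = cm$samples[cov],
      population = sheet$population[idx[cov]],
      replicate = sheet$replicate[idx[cov]],
      level = unname(v), z = unname((v - mu) / sdv),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(site_id = character(), chrom = character(),
                      pos = integer(), strand = character(),
                      sample_id = character(), population = character(),
                      replicate = integer(), level = numeric(), z = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call population-specific editing sites
#'
#' A site is called specific to a population when every replicate of that
#' population deviates in the same direction with |z| above `z_thresh`, and the
#' population's pooled editing level is at least `min_gap` away from the next
#' closest population's pooled level. The gap is an absolute editing-level
#' difference in fractions (0.10 = 10 percentage points), consistent with how
#' editing differences are quoted throughout this kind of analysis.
#'
#' @param zrec data.frame from [replicate_zscores()].
#' @param cm `edit_counts` at replicate resolution (for pooled levels).
#' @param sheet `sample_sheet`.
#' @param z_thresh replicate |z| threshold (default 1.65).
#' @param min_gap minimum pooled-level gap to the next closest population
#'   (default 0.10).
#' @return data.frame: site coordinates, population, direction ("high"/"low"),
#'   min_abs_z (the weakest replicate of the call), gap_to_next. A site may be
#'   called in two populations only in opposite directions.
#' @export
call_specific <- function(zrec, cm, sheet, z_thresh = 1.65, min_gap = 0.10) {
  pooled <- pool_replicates(cm, sheet)
  plv <- editing_levels(pooled)
  rownames(plv) <- site_id(pooled$sites)
  out <- list()
  for (sid in unique(zrec$site_id)) {
    zs <- zrec[zrec$site_id == sid, , drop = FALSE]
    n_reps <- table(sheet$population)
    for (pop in unique(zs$population)) {
      zp <- zs$z[zs$population == pop]
      # every replicate of the population must be covered and pass
      if (length(zp) < n_reps[[pop]]) next
      if (any(abs(zp) <= z_thresh)) next
      if (length(unique(sign(zp))) != 1) next
      levels_pooled <- plv[sid, ]
      this <- levels_pooled[[pop]]
      others <- levels_pooled[setdiff(names(levels_pooled), pop)]
      others <- others[!is.na(others)]
      if (!length(others) || is.na(this)) next
      gap <- min(abs(this - others))
      if (gap < min_gap) next
      out[[length(out) + 1L]] <- data.frame(
        site_id = sid, chrom = zs$chrom[1], pos = zs$pos[1],
        strand = zs$strand[1], population = pop,
        direction = if (sign(zp[1]) > 0) "high" else "low",
        min_abs_z = min(abs(zp)), gap_to_next = gap,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
    else data.frame(site_id = character(), chrom = character(),
                    pos = integer(), strand = character(),
                    population = character(), direction = character(),
                    min_abs_z = numeric(), gap_to_next = numeric(),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Annotation-category enrichment of a site set
#'
#' Chi-square comparison, per functional category, of the category's share
#' among a focal site set (e.g. population-specific sites) versus its share
#' among all tested sites (the background includes the focal set, mirroring
#' "X% of specific sites vs Y% of all sites tested").
#'
#' @param focal_sites sites data.frame (e.g. population-specific sites).
#' @param tested_sites sites data.frame of all sites tested.
#' @param annot annotation data.frame.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return data.frame per category: n_focal, n_tested, pct_focal, pct_tested,
#'   ratio, chi2, p_value.
#' @export
category_enrichment <- function(focal_sites, tested_sites, annot,
                                correct = FALSE) {
  cat_of <- function(s) {
    idx <- match(site_id(s), annot$site_id)
    out <- rep("intergenic", nrow(s))
    out[!is.na(idx)] <- annot$category[idx[!is.na(idx)]]
    out
  }
  fc <- cat_of(focal_sites); tc <- cat_of(tested_sites)
  cats <- c("nonsynonymous", "synonymous", "UTR3", "UTR5", "intron",
            "ncRNA", "intergenic")
  rows <- lapply(cats, function(cc) {
    n_f <- sum(fc == cc); n_t <- sum(tc == cc)
    tab <- matrix(c(n_f, length(fc) - n_f, n_t, length(tc) - n_t),
                  nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      chi2 <- NA_real_; p <- NA_real_
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
      chi2 <- unname(ct$statistic); p <- ct$p.value
    }
    data.frame(category = cc, n_focal = n_f, n_tested = n_t,
               pct_focal = 100 * n_f / max(1, length(fc)),
               pct_tested = 100 * n_t / max(1, length(tc)),
               ratio = (n_f / max(1, length(fc))) /
                 max(.Machine$double.eps, n_t / max(1, length(tc))),
               chi2 = chi2, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
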