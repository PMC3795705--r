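## The full cohort analysis battery: time-curve comparisons, degeneration
## and Modic-change group tests, correlations, univariate ANOVA models and
## the noise check, assembled into one tidy results table.

.res_row <- function(analysis, time, item, stat) {
  data.frame(analysis = analysis, time = time, item = item,
             statistic = stat$statistic, p = stat$p,
             significant = stat$significant,
             n = paste(stat$n, collapse = "/"),
             stringsAsFactors = FALSE)
}

.pairwise_rows <- function(analysis, time, stat) {
  pw <- stat$pairwise
  if (is.null(pw) || !nrow(pw)) return(NULL)
  data.frame(analysis = analysis, time = time,
             group1 = pw$group1, group2 = pw$group2, z = pw$z,
             p_adj = pw$p_adj, significant = pw$significant,
             stringsAsFactors = FALSE)
}

#' Run the full cohort analysis battery
#'
#' Executes, on a quantified cohort, the statistical battery of a
#' post-contrast disc transport study: Shapiro-Wilk normality gate;
#' per-ROI adjacent-time and per-time ROI-pair rank-sum comparisons on the
#' defect-free time-curve subset; Kruskal-Wallis + Dunn tests of central
#' disc enhancement across Pfirrmann grades and across Modic-change groups;
#' rank-sum tests for Modic changes (any vs none), endplate defects,
#' irregular endplates (vs all others and vs the remaining severely
#' degenerated discs); Spearman correlations of central enhancement with
#' the CSF-adjusted T2 index, age and disc height (all discs and the
#' Pfirrmann 1-3 subset); and three univariate ANOVA covariate sets for the
#' response at the 2 h, 4 h and 6 h time points.
#'
#' @param enhancement enhancement table ([quantify_cohort()] `$enhancement`).
#' @param quant per-disc CSF-adjusted T2 table (`$quant`).
#' @param meta cohort metadata (exclusions already applied).
#' @param heights per-disc landmark height estimates (`$heights`).
#' @param alpha significance level (default 0.05, two-sided throughout).
#' @return list with `results` (tidy rows: analysis, time, item, statistic,
#'   p, significant, n), `pairwise` (Dunn tables), `timecurves` (median and
#'   quartiles per ROI and time on the defect-free subset), `log`
#'   (skipped-comparison messages) and `report` (formatted text lines).
#' @export
run_paper_analyses <- function(enhancement, quant, meta, heights,
                               alpha = 0.05) {
  meta <- merge(meta, heights, by = "disc_id")
  meta <- merge(meta, quant[, c("disc_id", "csf_adj_t2")], by = "disc_id")
  meta$mc_any <- meta$mc_upper != "0" | meta$mc_lower != "0"
  meta$defect_any <- as.logical(meta$defect_upper) |
    as.logical(meta$defect_lower)
  meta$mc_grp <- mc_group(meta$mc_upper, meta$mc_lower)
  enhancement <- enhancement[enhancement$disc_id %in% meta$disc_id, ]

  post <- unique(enhancement$time[order(enhancement$minutes)])
  cen <- enhancement[enhancement$roi == "Central", ]
  cen_wide <- lapply(post, function(tl) {
    v <- cen$enhancement[cen$time == tl]
    names(v) <- cen$disc_id[cen$time == tl]
    v[meta$disc_id]
  })
  names(cen_wide) <- post

  results <- list(); pairwise <- list(); log <- character()
  add <- function(row) results[[length(results) + 1L]] <<- row
  addpw <- function(rows) if (!is.null(rows))
    pairwise[[length(pairwise) + 1L]] <<- rows
  skip <- function(msg) log[[length(log) + 1L]] <<- msg

  ## normality gate on central enhancement, pooled over post time points
  gate <- normality_gate(unlist(cen_wide, use.names = FALSE))
  add(data.frame(analysis = "normality_gate", time = "all", item = "central",
                 statistic = NA_real_, p = gate$p,
                 significant = isTRUE(gate$non_normal), n = length(cen_wide[[1]]),
                 stringsAsFactors = FALSE))

  ## time-curve subset comparisons
  tc_ids <- select_timecurve_subset(meta)
  tc <- enhancement[enhancement$disc_id %in% tc_ids, ]
  if (length(tc_ids) >= 3) {
    for (roi in unique(tc$roi)) {
      for (j in seq_len(length(post) - 1)) {
        x <- tc$enhancement[tc$roi == roi & tc$time == post[j]]
        y <- tc$enhancement[tc$roi == roi & tc$time == post[j + 1]]
        add(.res_row("timecurve_step", post[j + 1],
                     paste0(roi, ": ", post[j], " vs ", post[j + 1]),
                     rank_sum_test(x, y, exact = FALSE)))
      }
    }
    roi_pairs <- list(c("SCB_upper", "EPZ_upper"), c("SCB_lower", "EPZ_lower"),
                      c("EPZ_upper", "Peripheral_upper"),
                      c("EPZ_lower", "Peripheral_lower"),
                      c("Peripheral_upper", "Central"),
                      c("Peripheral_lower", "Central"))
    for (tl in post) for (pr in roi_pairs) {
      x <- tc$enhancement[tc$roi == pr[1] & tc$time == tl]
      y <- tc$enhancement[tc$roi == pr[2] & tc$time == tl]
      add(.res_row("timecurve_roi_pair", tl, paste(pr, collapse = " vs "),
                   rank_sum_test(x, y, exact = FALSE)))
    }
  } else skip("time-curve subset too small; ROI comparisons skipped")

  ## Pfirrmann grades: central enhancement and CSF-adjusted T2
  for (tl in post) {
    if (length(unique(meta$pfirrmann)) >= 3) {
      st <- kruskal_dunn(cen_wide[[tl]], meta$pfirrmann, alpha)
      add(.res_row("pfirrmann_kw", tl, "central", st))
      addpw(.pairwise_rows("pfirrmann_kw", tl, st))
    } else skip(paste("fewer than 3 Pfirrmann groups at", tl))
  }
  if (length(unique(meta$pfirrmann)) >= 3) {
    st <- kruskal_dunn(meta$csf_adj_t2, meta$pfirrmann, alpha)
    add(.res_row("csf_t2_pfirrmann_kw", "T2", "csf_adj_t2", st))
    addpw(.pairwise_rows("csf_t2_pfirrmann_kw", "T2", st))
  }

  ## Spearman correlations of central enhancement
  low <- meta$pfirrmann <= 3
  for (tl in post) {
    for (var in c("csf_adj_t2", "age", "height_mm")) {
      add(.res_row("spearman_all", tl, var,
                   spearman_cor(meta[[var]], cen_wide[[tl]])))
      if (sum(low) >= 3)
        add(.res_row("spearman_pf123", tl, var,
                     spearman_cor(meta[[var]][low], cen_wide[[tl]][low])))
    }
  }
  add(.res_row("spearman_csf_t2", "T2", "age",
               spearman_cor(meta$age, meta$csf_adj_t2)))
  add(.res_row("spearman_csf_t2", "T2", "height_mm",
               spearman_cor(meta$height_mm, meta$csf_adj_t2)))

  ## Modic changes
  for (tl in post) {
    if (any(meta$mc_any) && any(!meta$mc_any)) {
      add(.res_row("mc_any", tl, "MC vs none",
                   rank_sum_test(cen_wide[[tl]][meta$mc_any],
                                 cen_wide[[tl]][!meta$mc_any], exact = FALSE)))
    } else skip(paste("MC group empty at", tl))
    grp <- meta$mc_grp
    use <- grp != "MCIII"
    if (length(unique(grp[use])) >= 3) {
      st <- kruskal_dunn(cen_wide[[tl]][use], grp[use], alpha)
      add(.res_row("mc_type_kw", tl, "central", st))
      addpw(.pairwise_rows("mc_type_kw", tl, st))
    }
  }

  ## endplate defects and irregular endplates
  sev <- meta$pfirrmann >= 4
  for (tl in post) {
    if (any(meta$defect_any) && any(!meta$defect_any))
      add(.res_row("defect_any", tl, "defect vs none",
                   rank_sum_test(cen_wide[[tl]][meta$defect_any],
                                 cen_wide[[tl]][!meta$defect_any],
                                 exact = FALSE)))
    if (any(meta$irregular) && any(!meta$irregular))
      add(.res_row("irregular", tl, "irregular vs rest",
                   rank_sum_test(cen_wide[[tl]][meta$irregular],
                                 cen_wide[[tl]][!meta$irregular],
                                 exact = FALSE)))
    if (any(meta$irregular) && any(sev & !meta$irregular))
      add(.res_row("irregular_vs_severe", tl, "irregular vs Pf4-5",
                   rank_sum_test(cen_wide[[tl]][meta$irregular],
                                 cen_wide[[tl]][sev & !meta$irregular],
                                 exact = FALSE)))
  }

  ## univariate ANOVA covariate sets at the late time points
  late <- intersect(c("POST_2H", "POST_4H", "POST_6H"), post)
  model_sets <- list(
    model1 = list(cov = c("height_mm", "defect_any", "mc_any", "pfirrmann"),
                  fac = c("defect_any", "mc_any", "pfirrmann")),
    model2 = list(cov = c("height_mm", "defect_any", "mc_any", "csf_adj_t2"),
                  fac = c("defect_any", "mc_any")),
    model3 = list(cov = c("height_mm", "irregular", "mc_any", "pfirrmann"),
                  fac = c("irregular", "mc_any", "pfirrmann")))
  for (tl in late) {
    d <- meta
    d$response <- cen_wide[[tl]]
    for (mn in names(model_sets)) {
      ms <- model_sets[[mn]]
      tab <- tryCatch(
        univariate_anova(d, "response", ms$cov, ms$fac),
        error = function(e) { skip(paste("anova", mn, tl, "skipped:",
                                         conditionMessage(e))); NULL })
      if (!is.null(tab)) {
        for (i in seq_len(nrow(tab)))
          add(data.frame(analysis = paste0("anova_", mn), time = tl,
                         item = tab$variable[i], statistic = tab$F[i],
                         p = tab$p[i], significant = tab$p[i] < alpha,
                         n = nrow(d), stringsAsFactors = FALSE))
      }
    }
  }

  results <- do.call(rbind, results)
  pairwise <- if (length(pairwise)) do.call(rbind, pairwise) else NULL
  timecurves <- if (length(tc_ids))
    assemble_timecurves(enhancement, tc_ids) else NULL

  report <- c(
    sprintf("Cohort analysis: %d discs (%d in time-curve subset), alpha = %g",
            nrow(meta), length(tc_ids), alpha),
    sprintf("Normality gate: Shapiro-Wilk p = %.3g (%s)", gate$p,
            if (isTRUE(gate$non_normal)) "non-normal; nonparametric tests"
            else "no departure detected"),
    sprintf("%-22s %-10s %-38s %10s %9s %s", "analysis", "time", "item",
            "statistic", "p", "sig"),
    sprintf("%-22s %-10s %-38s %10.3f %9.3g %s", results$analysis,
            results$time, strtrim(results$item, 38), results$statistic,
            results$p, ifelse(results$significant, "*", "")),
    if (length(log)) c("Skipped:", paste(" -", log)) else character())

  list(results = results, pairwise = pairwise, timecurves = timecurves,
       log = log, report = report)
}
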