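#' Run the full flexibility analysis on one condition
#'
#' Orchestrates the standard pipeline: equilibration trimming, rigid-body
#' superposition, polygonal axis construction, tangent-correlation profile,
#' persistence-length fits (least-squares and secant), local flexibility,
#' region-wise main-chain hydrogen bonds, and the inter-helix distance
#' profile.  Errors raised by a stage are rethrown with the stage name
#' attached.
#'
#' @param ens A [conformation_ensemble].
#' @param name Condition label (e.g. `"unXL"`, `"XL"`).
#' @param scheme A [segment_scheme()].
#' @param t_start_ps Equilibration cutoff; frames before it are dropped
#'   (0 keeps everything).
#' @param align Superpose frames before the tangent analysis (recommended
#'   for free trajectories; synthetic clamped ensembles need no alignment).
#' @param selection [selection_spec()] for the superposition.  The default
#'   anchors the body frame on the C-alpha atoms of the scheme's *first*
#'   segment (both chains): fluctuations then grow along the chain and the
#'   tangent correlation decays exponentially with contour distance, which
#'   is the frame the worm-like-chain law presumes.  Aligning on the whole
#'   molecule instead spreads the fluctuations symmetrically and destroys
#'   the decay (see the methods vignette).
#' @param regions H-bond region table, or `NULL` to skip the H-bond stage
#'   (e.g. for C-alpha-only ensembles).
#' @param criterion An [hbond_criterion()].
#' @param n_blocks Contiguous blocks for SEMs and block-wise Lp estimates.
#' @param temperature_K Kelvin; defaults to the ensemble's temperature.
#' @param intercept Free intercept in the least-squares fit.
#' @return A `condition_summary`; see [condition_summary()] for fields.
#' @export
run_analysis <- function(ens, name = "condition", scheme = segment_scheme(),
                         t_start_ps = 0, align = TRUE, selection = NULL,
                         regions = NULL, criterion = hbond_criterion(),
                         n_blocks = 8, temperature_K = NULL,
                         intercept = TRUE) {
  temperature_K <- temperature_K %||% attr(ens, "temperature_K")
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage ", label, ": ", conditionMessage(e)))
    })
  }
  if (t_start_ps > 0) {
    ens <- stage("trim_equilibration", trim_equilibration(ens, t_start_ps))
  }
  if (align) {
    selection <- selection %||% selection_spec(
      residue_range = c(scheme$segments$res_first[1],
                        scheme$segments$res_last[1]))
    ens <- stage("superpose", superpose(ens, selection))
  }
  axis <- stage("build_axis", build_axis(ens, scheme))
  profile <- stage("correlation_profile",
                   correlation_profile(axis, n_blocks = n_blocks))
  fit_ls <- stage("fit_lp_least_squares",
                  fit_lp(profile, temperature_K, "least_squares",
                         intercept = intercept))
  fit_sec <- stage("fit_lp_secant", fit_lp(profile, temperature_K, "secant"))
  flex <- stage("flexibility_profile", flexibility_profile(profile, scheme))
  blocks_ls <- stage("blockwise_lp",
                     blockwise_lp(axis, n_blocks, temperature_K,
                                  "least_squares", intercept = intercept))
  distances <- stage("helix_distance_profile",
                     helix_distance_profile(ens, scheme))
  hbonds <- if (!is.null(regions)) {
    stage("region_hbond_stats", region_hbond_stats(ens, regions, criterion))
  } else NULL
  condition_summary(
    name = name, temperature_K = temperature_K,
    lp_ls = fit_ls$lp_nm, lp_secant = fit_sec$lp_nm,
    lp_ls_se = fit_ls$lp_se_nm, hbonds = hbonds,
    blocks_ls = blocks_ls, profile = profile, flexibility = flex,
    distances = distances, fits = list(least_squares = fit_ls,
                                       secant = fit_sec),
    n_frames = attr(profile, "n_frames")
  )
}

#' Summary of one analysed condition
#'
#' Container for the quantities the comparison report consumes.  Usually
#' produced by [run_analysis()], but it can be built directly from reported
#' numbers (e.g. published persistence lengths and H-bond means) to run
#' the ratio / percent-change / significance arithmetic on them.
#'
#' @param name Condition label.
#' @param temperature_K Kelvin (or any consistent temperature key).
#' @param lp_ls,lp_secant Persistence lengths (nm) from the least-squares
#'   and secant estimators.
#' @param lp_ls_se Standard error of `lp_ls`, nm.
#' @param hbonds H-bond summary tibble (`region`, `mean`, `sd`), or `NULL`.
#' @param blocks_ls Block-wise least-squares Lp estimates (for t-tests).
#' @param profile,flexibility,distances,fits,n_frames Optional full
#'   pipeline outputs.
#' @return A `condition_summary` list.
#' @export
condition_summary <- function(name, temperature_K, lp_ls, lp_secant,
                              lp_ls_se = NA_real_, hbonds = NULL,
                              blocks_ls = NULL, profile = NULL,
                              flexibility = NULL, distances = NULL,
                              fits = NULL, n_frames = NA_integer_) {
  if (lp_ls <= 0 || lp_secant <= 0) abort("persistence lengths must be positive")
  structure(list(
    name = name, temperature_K = temperature_K, lp_ls = lp_ls,
    lp_secant = lp_secant, lp_ls_se = lp_ls_se, hbonds = hbonds,
    blocks_ls = blocks_ls, profile = profile, flexibility = flexibility,
    distances = distances, fits = fits, n_frames = n_frames
  ), class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> %s @ %g K: Lp = %.1f nm (secant %.1f)\n",
              x$name, x$temperature_K, x$lp_ls, x$lp_secant))
  if (!is.null(x$hbonds)) {
    cat("  H-bonds:\n")
    for (i in seq_len(nrow(x$hbonds))) {
      cat(sprintf("    %-18s %.1f +/- %.1f\n", x$hbonds$region[i],
                  x$hbonds$mean[i], x$hbonds$sd[i]))
    }
  }
  invisible(x)
}

#' Percent change between two values
#'
#' Signed percent change from `from` to `to`, `(to - from)/from * 100`;
#' e.g. a drop from 9.7 to 6.1 is -37 (a 37% decrease).
#'
#' @param from Baseline value (non-zero).
#' @param to New value.
#' @return Percent change (negative = decrease).
#' @export
percent_change <- function(from, to) {
  if (any(from == 0)) abort("baseline of a percent change must be non-zero")
  (to - from) / from * 100
}

#' Cross-condition comparison report
#'
#' Reproduces the standard table arithmetic for a set of analysed
#' conditions: persistence-length ratios versus a reference condition at
#' the same temperature, displayed to two decimals as
#' `"least-squares(secant)"`; percent changes of each region's mean H-bond
#' count between temperatures within a condition (nearest percent); and
#' Student's t-tests on block-wise Lp estimates against the reference where
#' blocks are available.  Full precision is retained in the returned
#' tibbles; only the `_label` columns are rounded for display.
#'
#' @param summaries List of `condition_summary` objects.
#' @param reference Name of the reference (denominator) condition.
#' @return A `comparison_report` list with tibbles `lp` (per condition:
#'   Lp values, ratios, labels, t-test p-values), `hbond_changes`
#'   (per condition/region percent change across temperatures), and the
#'   input `summaries`.
#' @export
compare_conditions <- function(summaries, reference) {
  if (length(summaries) < 2) abort("need at least two conditions")
  names_ <- vapply(summaries, function(s) s$name, character(1))
  temps <- vapply(summaries, function(s) s$temperature_K, numeric(1))
  if (!reference %in% names_) {
    abort(paste0("reference condition ", reference, " not among summaries"))
  }
  ref_of <- function(temp) {
    hit <- which(names_ == reference & temps == temp)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }

  lp_rows <- purrr::map_dfr(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    ri <- ref_of(s$temperature_K)
    if (is.na(ri)) {
      ratio_ls <- ratio_sec <- NA_real_
      p_val <- NA_real_
    } else {
      r <- summaries[[ri]]
      ratio_ls <- s$lp_ls / r$lp_ls
      ratio_sec <- s$lp_secant / r$lp_secant
      p_val <- if (!is.null(s$blocks_ls) && !is.null(r$blocks_ls) && i != ri) {
        tryCatch(
          compare_lp(list(lp_nm = s$lp_ls), list(lp_nm = r$lp_ls),
                     s$blocks_ls, r$blocks_ls)$p_value,
          error = function(e) NA_real_)
      } else if (i == ri) 1 else NA_real_
    }
    tibble(
      condition = s$name, temperature_K = s$temperature_K,
      lp_ls_nm = s$lp_ls, lp_secant_nm = s$lp_secant,
      lp_label = sprintf("%.1f (%.1f)", s$lp_ls, s$lp_secant),
      ratio_ls = ratio_ls, ratio_secant = ratio_sec,
      ratio_label = if (is.na(ratio_ls)) NA_character_ else
        sprintf("%.2f(%.2f)", ratio_ls, ratio_sec),
      p_value_vs_ref = p_val
    )
  })

  hb_rows <- purrr::map_dfr(unique(names_), function(nm) {
    idx <- which(names_ == nm)
    if (length(idx) < 2) return(tibble())
    idx <- idx[order(temps[idx])]
    base <- summaries[[idx[1]]]
    purrr::map_dfr(idx[-1], function(j) {
      s <- summaries[[j]]
      if (is.null(base$hbonds) || is.null(s$hbonds)) return(tibble())
      joined <- dplyr::inner_join(base$hbonds, s$hbonds, by = "region",
                                  suffix = c("_from", "_to"))
      tibble(
        condition = nm, region = joined$region,
        temperature_from_K = base$temperature_K,
        temperature_to_K = s$temperature_K,
        mean_from = joined$mean_from, mean_to = joined$mean_to,
        pct_change = percent_change(joined$mean_from, joined$mean_to),
        pct_label = sprintf("%+d%%",
                            as.integer(round(percent_change(
                              joined$mean_from, joined$mean_to))))
      )
    })
  })

  structure(list(lp = lp_rows, hbond_changes = hb_rows,
                 reference = reference, summaries = summaries),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> reference: %s\n", x$reference))
  print(x$lp[, c("condition", "temperature_K", "lp_label", "ratio_label",
                 "p_value_vs_ref")])
  if (nrow(x$hbond_changes) > 0) {
    cat("H-bond changes across temperature:\n")
    print(x$hbond_changes[, c("condition", "region", "mean_from", "mean_to",
                              "pct_label")])
  }
  invisible(x)
}

#' Export report artifacts as TSV/JSON
#'
#' Writes the correlation profile, flexibility profile and distance profile
#' of each condition as TSV, and the persistence estimates plus comparison
#' tables as JSON, into `dir`.
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in report$summaries) {
    tag <- sprintf("%s_%gK", gsub("[^A-Za-z0-9]", "_", s$name),
                   s$temperature_K)
    if (!is.null(s$profile)) {
      p <- file.path(dir, paste0(tag, "_correlation.tsv"))
      prof <- as_tibble(s$profile)
      prof$ln_c <- log(prof$c)
      readr::write_tsv(prof, p, progress = FALSE)
      paths <- c(paths, p)
    }
    if (!is.null(s$flexibility)) {
      p <- file.path(dir, paste0(tag, "_flexibility.tsv"))
      readr::write_tsv(as_tibble(s$flexibility), p, progress = FALSE)
      paths <- c(paths, p)
    }
    if (!is.null(s$distances)) {
      p <- file.path(dir, paste0(tag, "_distances.tsv"))
      readr::write_tsv(s$distances, p, progress = FALSE)
      paths <- c(paths, p)
    }
    if (!is.null(s$hbonds)) {
      p <- file.path(dir, paste0(tag, "_hbonds.tsv"))
      readr::write_tsv(s$hbonds, p, progress = FALSE)
      paths <- c(paths, p)
    }
  }
  p <- file.path(dir, "comparison.json")
  jsonlite::write_json(
    list(reference = report$reference, lp = report$lp,
         hbond_changes = report$hbond_changes),
    p, auto_unbox = TRUE, digits = NA, na = "null")
  paths <- c(paths, p)
  invisible(paths)
}
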