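#' Classify the motional regime of a site
#'
#' Joins the dipolar order parameter with the Arrhenius evidence into one
#' of three labels: `"fast"` when the order parameter is at or below
#' `s2_fast` and the motion sits on the fast branch (motional frequencies
#' above the probe frequency); `"rigid"` when the order parameter is at or
#' above `s2_rigid` and the rate series is flat (activation energy below
#' `flat_E_max`, or no rate evidence contradicting rigidity);
#' `"intermediate"` otherwise. The thresholds are configuration labels,
#' not physical claims.
#'
#' @param S2 dipolar order parameter (NA when unavailable).
#' @param E_star activation energy, kJ mol^-1 (NA when unavailable).
#' @param branch `"fast"`, `"slow"` or NA.
#' @param thresholds list with `s2_fast` (default 0.5), `s2_rigid` (0.95),
#'   `flat_E_max` (2 kJ mol^-1).
#' @return `"fast"`, `"rigid"` or `"intermediate"`.
#' @export
classify_regime <- function(S2, E_star = NA, branch = NA,
                            thresholds = list()) {
  th <- utils::modifyList(list(s2_fast = 0.5, s2_rigid = 0.95, flat_E_max = 2),
                          thresholds)
  if (!is.na(S2) && S2 <= th$s2_fast && (is.na(branch) || branch == "fast"))
    return("fast")
  flat <- is.na(E_star) || E_star <= th$flat_E_max
  if (!is.na(S2) && S2 >= th$s2_rigid && flat) return("rigid")
  "intermediate"
}

#' Run the end-to-end regime analysis
#'
#' Orchestrates the stages (thermal analysis, relaxation, dipolar
#' couplings, motional models) over a set of sites and emits a per-site
#' regime report. The configuration is a YAML file or an equivalent list:
#'
#' ```yaml
#' thresholds: {s2_fast: 0.5, s2_rigid: 0.95, flat_E_max: 2}
#' d_rig_kHz: 13.5          # post-scaling rigid limit for S2
#' dsc:
#'   trace: dsc.csv         # optional; heat-flow CSV
#'   transitions: [{T_K: 272, window: [262, 282]}, {T_K: 232, window: [222, 242]}]
#' sites:
#'   - name: esterCH2
#'     temperature_range: [275, 320]
#'     rates: rates_C22.csv       # rate_series CSV
#'     pattern: pake_C22.csv      # dipolar_pattern CSV
#' ```
#'
#' Per site, `pattern` (path or `dipolar_pattern`) yields the order
#' parameter via [fit_pattern()]; `rates` (path or `rate_series`) yields
#' the activation energy and branch via [arrhenius_fit()]. A missing
#' input degrades only that evidence column (recorded as `NA`); a path
#' that does not exist raises an error naming the stage. Wobble/jump
#' interpretations of the order parameter are attached as evidence.
#'
#' @param config path to a YAML file or a list as above.
#' @param out_dir optional directory; when given, the report is written as
#'   `regime_report.json` and `regime_report.md` (deterministic content,
#'   no timestamps) together with a provenance log of input file hashes.
#' @return object of class `regime_report`: data.frame with one row per
#'   site (`site`, `T_lo`, `T_hi`, `S2`, `E_star`, `branch`, `tau_hint`,
#'   `regime`), with DSC transitions in `attr(, "transitions")`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  th <- cfg$thresholds %||% list()
  d_rig <- cfg$d_rig_kHz %||% rigid_limit_D()
  hashes <- character()
  load_input <- function(x, type, stage) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) {
      if (!file.exists(x))
        stop_invalid("stage '%s': input file %s not found", stage, x)
      hashes[[x]] <<- unname(tools::md5sum(x))
      return(read_spindyn_csv(x, type = type))
    }
    x
  }
  # thermal stage
  transitions <- NULL
  if (!is.null(cfg$dsc)) {
    trace <- load_input(cfg$dsc$trace, "dsc", "thermo")
    if (!is.null(trace)) {
      transitions <- do.call(rbind, lapply(cfg$dsc$transitions, function(tr) {
        w <- if (!is.null(tr$window)) unlist(tr$window) else tr$T_K + c(-10, 10)
        t <- characterize_transition(trace, tr$T_K, window = w)
        data.frame(T_K = t$T_trans, dH_kJmol = t$dH_kJmol, dS_JmolK = t$dS_JmolK)
      }))
    }
  }
  rows <- lapply(cfg$sites, function(sc) {
    S2 <- NA_real_; E_star <- NA_real_; branch <- NA_character_; tau_hint <- NA_real_
    pat <- load_input(sc$pattern, "pattern", sprintf("dipolar[%s]", sc$name))
    if (!is.null(pat)) {
      res <- fit_pattern(pat, D_rig = sc$d_rig_kHz %||% d_rig)
      S2 <- res$S2
    }
    rs <- load_input(sc$rates, "rates", sprintf("relax[%s]", sc$name))
    if (!is.null(rs)) {
      fit <- arrhenius_fit(rs, window = if (!is.null(sc$temperature_range))
        unlist(sc$temperature_range) else NULL)
      E_star <- fit$E_star
      branch <- fit$branch
      if (attr(rs, "frame") == "rotating" && !is.na(attr(rs, "spin_lock_nu")))
        tau_hint <- r1rho_max_tau(attr(rs, "spin_lock_nu"))
    }
    tr <- if (!is.null(sc$temperature_range)) unlist(sc$temperature_range) else c(NA, NA)
    data.frame(site = sc$name, T_lo = tr[1], T_hi = tr[2],
               S2 = S2, E_star = E_star, branch = branch, tau_hint = tau_hint,
               regime = classify_regime(S2, E_star, branch, th))
  })
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  attr(rep, "transitions") <- transitions
  attr(rep, "thresholds") <- utils::modifyList(
    list(s2_fast = 0.5, s2_rigid = 0.95, flat_E_max = 2), th)
  attr(rep, "input_hashes") <- hashes
  class(rep) <- c("regime_report", "data.frame")
  if (!is.null(out_dir)) write_regime_report(rep, out_dir)
  rep
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a regime report as JSON and Markdown
#'
#' @param report a `regime_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_regime_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(sites = as.data.frame(report),
                  transitions = attr(report, "transitions"),
                  thresholds = attr(report, "thresholds"),
                  input_hashes = as.list(attr(report, "input_hashes")))
  jsonlite::write_json(payload, file.path(out_dir, "regime_report.json"),
                       auto_unbox = TRUE, digits = 10, null = "null",
                       dataframe = "rows", pretty = TRUE)
  df <- as.data.frame(report)
  fmt <- function(x) ifelse(is.na(x), "-", formatC(x, digits = 3, format = "g"))
  md <- c("# Motional regime report", "",
          "| site | T range (K) | S2 | E* (kJ/mol) | branch | regime |",
          "|---|---|---|---|---|---|",
          sprintf("| %s | %s-%s | %s | %s | %s | %s |",
                  df$site, fmt(df$T_lo), fmt(df$T_hi), fmt(df$S2),
                  fmt(df$E_star), ifelse(is.na(df$branch), "-", df$branch),
                  df$regime))
  tr <- attr(report, "transitions")
  if (!is.null(tr)) {
    md <- c(md, "", "## DSC transitions", "",
            "| T (K) | dH (kJ/mol) | dS (J/mol/K) |", "|---|---|---|",
            sprintf("| %s | %s | %s |", fmt(tr$T_K), fmt(tr$dH_kJmol), fmt(tr$dS_JmolK)))
  }
  writeLines(md, file.path(out_dir, "regime_report.md"))
  invisible(out_dir)
}

#' @export
print.regime_report <- function(x, ...) {
  cat(sprintf("<regime_report> %d site(s)\n", nrow(x)))
  print(as.data.frame(x))
  invisible(x)
}
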