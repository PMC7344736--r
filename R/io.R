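#' Read a pipeline run configuration
#'
#' A run configuration is a single YAML file with per-arm sections and the
#' model settings. Counts paths are resolved relative to the config file.
#' Recognised keys: \code{arms} (list of \code{name}, \code{counts} file,
#' \code{cost}, optional \code{cost_sd}, \code{n_patients}, \code{format});
#' \code{utilities} (per-state values, optional \code{deduction_mode});
#' \code{discount} (\code{cost}, \code{qaly}); \code{horizon} (\code{mode},
#' \code{n_cycles}, \code{epsilon}, \code{cap}); \code{thresholds};
#' \code{psa} (\code{n}); \code{dsa} (\code{delta}); \code{horizons};
#' \code{seed}.
#'
#' @param path Path to a YAML config file.
#' @return A list with \code{strategies} (list of \code{\link{strategy}}),
#'   \code{utilities}, \code{discount}, \code{horizon}, \code{thresholds},
#'   \code{psa_n}, \code{dsa_delta}, \code{horizons}, \code{seed} and the
#'   raw \code{config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  if (is.null(cfg$arms) || !length(cfg$arms)) {
    stop("config has no arms", call. = FALSE)
  }
  strategies <- lapply(cfg$arms, function(a) {
    if (is.null(a$name) || is.null(a$counts) || is.null(a$cost)) {
      stop("each arm needs name, counts and cost", call. = FALSE)
    }
    cpath <- a$counts
    if (!file.exists(cpath)) cpath <- file.path(base, a$counts)
    cnt <- read_counts(cpath, format = a$format %||% "long", arm = a$name)
    strategy(a$name, estimate_transition_matrix(cnt),
             upfront_cost = a$cost, cost_sd = a$cost_sd %||% NA_real_,
             n_patients = a$n_patients %||% NA_integer_)
  })
  u <- cfg$utilities %||% list()
  utilities <- utility_set(
    stable = u$stable %||% 0.620, recurrence = u$recurrence %||% 0.767,
    metastasis = u$metastasis %||% 0.692,
    deduction_mode = u$deduction_mode %||% "off")
  d <- cfg$discount %||% list()
  discount <- discount_spec(cost = d$cost %||% 0.03, qaly = d$qaly %||% 0.03)
  h <- cfg$horizon %||% list()
  horizon <- horizon_spec(mode = h$mode %||% "fixed",
                          n_cycles = h$n_cycles %||% 20,
                          epsilon = h$epsilon %||% 0.001,
                          cap = h$cap %||% 100)
  list(strategies = strategies, utilities = utilities, discount = discount,
       horizon = horizon,
       thresholds = unlist(cfg$thresholds) %||% c(20000, 40000, 60000),
       psa_n = cfg$psa$n %||% 1000, dsa_delta = cfg$dsa$delta %||% 0.1,
       horizons = unlist(cfg$horizons) %||% c(5, 10, 15, 20),
       seed = cfg$seed %||% 1L, config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a transition matrix, count table or cohort trace as delimited text
#'
#' Matrices and count tables are written as labelled wide grids; traces get a
#' 0-based \code{cycle} column. Values are written at full precision; any
#' rounding is presentation-only (see \code{\link{write_report}}).
#'
#' @param x A \code{transition_matrix}, \code{transition_counts} or
#'   \code{markov_trace}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_matrix <- function(x, path) {
  df <- as.data.frame(unclass(x))
  label <- if (inherits(x, "markov_trace")) "cycle" else "from_state"
  df <- cbind(stats::setNames(data.frame(rownames(df)), label), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render a human-readable analysis report
#'
#' Presentation rounding only: probabilities to 3 decimals, money to 2,
#' QALYs to 4. Sections with no content are omitted with a note. Dominated
#' or dominant comparisons print their flag, not a number, in the ICER
#' column.
#'
#' @param results A named list with any of \code{summary} (a
#'   \code{\link{summary.cea_model}}), \code{tornado}, \code{ceac},
#'   \code{sweep}, \code{psa}.
#' @param file A connection or file path, default stdout.
#' @return Invisibly, the printed lines.
#' @export
write_report <- function(results, file = stdout()) {
  lines <- character()
  add <- function(...) lines <<- c(lines, sprintf(...))
  money <- function(x) formatC(x, format = "f", digits = 2)
  add("Cost-effectiveness analysis report")
  add("==================================")
  if (!is.null(results$summary)) {
    s <- results$summary
    add("")
    add("Per-strategy totals (%s horizon):", s$horizon$mode)
    df <- s$results
    for (i in seq_len(nrow(df))) {
      add("  %-36s cost %12s  QALYs %8.4f", df$strategy[i], money(df$cost[i]),
          df$qalys[i])
    }
    if (!is.null(s$frontier)) {
      add("")
      add("Incremental analysis (efficiency frontier):")
      fr <- s$frontier
      for (i in seq_len(nrow(fr))) {
        icer_txt <- if (fr$status[i] != "frontier") fr$status[i]
        else if (is.na(fr$icer[i])) "(reference)"
        else paste0(money(fr$icer[i]), " EUR/QALY vs ", fr$comparator[i])
        add("  %-36s %s", fr$strategy[i], icer_txt)
      }
    }
  }
  if (!is.null(results$tornado)) {
    add("")
    add("One-way sensitivity analysis (tornado order):")
    tn <- results$tornado
    for (i in seq_len(nrow(tn))) {
      add("  %-28s low %12s  high %12s  range %12s", tn$parameter[i],
          money(tn$low[i]), money(tn$high[i]), money(tn$range[i]))
    }
  }
  if (!is.null(results$psa) || !is.null(results$ceac)) {
    add("")
    if (is.null(results$ceac)) {
      add("Probabilistic sensitivity analysis: no acceptability table")
    } else {
      add("Acceptability (fraction of simulations most cost-effective):")
      cc <- results$ceac
      for (lam in unique(cc$threshold)) {
        add("  threshold %s EUR/QALY:", money(lam))
        sub <- cc[cc$threshold == lam, ]
        for (i in seq_len(nrow(sub))) {
          add("    %-34s %5.1f%%", sub$strategy[i], 100 * sub$fraction[i])
        }
      }
    }
  } else {
    add("")
    add("(no probabilistic sensitivity analysis in this run)")
  }
  if (!is.null(results$sweep)) {
    add("")
    add("ICER by time horizon:")
    sw <- results$sweep
    for (i in seq_len(nrow(sw))) {
      add("  %4s cycles  %-34s %s", sw$horizon[i], sw$intervention[i],
          if (sw$flag[i] == "ratio") paste0(money(sw$icer[i]), " EUR/QALY")
          else sw$flag[i])
    }
  }
  writeLines(lines, file)
  invisible(lines)
}

#' Command-line entry point
#'
#' Subcommand dispatcher used by the \code{inst/cli/markovcea} Rscript shim.
#' Subcommands: \code{estimate} (counts file to estimated matrix),
#' \code{run} (full pipeline from a config: CE tables for the configured and
#' lifetime horizons, tornado, PSA draws, CEAC, horizon sweep, manifest and
#' report), \code{icer} (ICER of two cost/QALY pairs), \code{dsa},
#' \code{psa}, \code{horizon-sweep}, \code{simulate} (synthetic cohort),
#' \code{fixtures} (write the built-in case-study inputs as files).
#' Common flags: \code{--config}, \code{--seed}, \code{--out},
#' \code{--verbose}.
#'
#' Errors are reported on stderr with a nonzero status; logs go to stderr,
#' outputs to files or stdout only.
#'
#' @param args Character vector of command-line arguments (excluding the
#'   program name).
#' @return Invisibly, an integer exit status (0 on success).
#' @export
cea_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) stop("usage: markovcea <subcommand> [flags]", call. = FALSE)
    cmd <- args[1L]
    opts <- parse_cli_flags(args[-1L])
    switch(cmd,
           estimate = cli_estimate(opts),
           run = cli_run(opts),
           icer = cli_icer(opts),
           dsa = cli_dsa(opts),
           psa = cli_psa(opts),
           `horizon-sweep` = cli_sweep(opts),
           simulate = cli_simulate(opts),
           fixtures = cli_fixtures(opts),
           stop("unknown subcommand: ", cmd, call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (key == "verbose") {
      opts$verbose <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args)) stop("flag --", key, " needs a value", call. = FALSE)
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

cli_log <- function(opts, ...) {
  if (isTRUE(opts$verbose)) message(...)
}

cli_estimate <- function(opts) {
  if (is.null(opts$counts)) stop("estimate needs --counts", call. = FALSE)
  cnt <- read_counts(opts$counts, format = opts$format %||% "long")
  cli_log(opts, "row totals: ",
          paste(rownames(cnt), rowSums(cnt), sep = "=", collapse = ", "))
  m <- estimate_transition_matrix(cnt)
  if (is.null(opts$out)) {
    df <- as.data.frame(round(unclass(m), 3))
    utils::write.csv(cbind(from_state = rownames(df), df), row.names = FALSE,
                     quote = FALSE)
  } else {
    write_matrix(m, opts$out)
  }
  invisible(m)
}

cli_build_model <- function(opts) {
  if (is.null(opts$config)) stop("missing --config", call. = FALSE)
  rc <- read_run_config(opts$config)
  if (!is.null(opts$seed)) rc$seed <- as.integer(opts$seed)
  rc$model <- cea_model(rc$strategies, rc$utilities, rc$discount, rc$horizon)
  rc
}

cli_run <- function(opts) {
  rc <- cli_build_model(opts)
  out <- opts$out %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  mod <- rc$model
  life <- predict(mod, horizon = "lifetime")
  ce <- rbind(cbind(horizon = rc$horizon$mode, mod$results),
              cbind(horizon = "lifetime", life$results))
  utils::write.csv(ce, file.path(out, "ce_table.csv"), row.names = FALSE)
  tn <- tornado(mod, delta = rc$dsa_delta)
  utils::write.csv(tn, file.path(out, "tornado.csv"), row.names = FALSE)
  psa <- simulate(mod, nsim = rc$psa_n, seed = rc$seed)
  utils::write.csv(psa$draws, file.path(out, "psa_draws.csv"), row.names = FALSE)
  cc <- ceac(psa, rc$thresholds)
  utils::write.csv(cc, file.path(out, "ceac.csv"), row.names = FALSE)
  sw <- horizon_sweep(mod, rc$horizons)
  utils::write.csv(sw, file.path(out, "horizon_sweep.csv"), row.names = FALSE)
  manifest <- list(seed = rc$seed,
                   config = normalizePath(opts$config),
                   config_hash = config_hash(opts$config),
                   package_version = as.character(utils::packageVersion("markovcea")),
                   r_version = R.version.string,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  write_report(list(summary = summary(mod), tornado = tn, ceac = cc,
                    sweep = sw, psa = psa),
               file.path(out, "report.txt"))
  cli_log(opts, "wrote results to ", out)
  invisible(out)
}

config_hash <- function(path) {
  # content fingerprint without extra dependencies: sum of a fast rolling hash
  raw <- readBin(path, "raw", file.size(path))
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251)) %% 2^31)
}

cli_icer <- function(opts) {
  need <- c("cost-ref", "qaly-ref", "cost-alt", "qaly-alt")
  if (!all(need %in% names(opts))) {
    stop("icer needs --cost-ref --qaly-ref --cost-alt --qaly-alt", call. = FALSE)
  }
  e <- icer(ce_result("reference", as.numeric(opts[["cost-ref"]]),
                      as.numeric(opts[["qaly-ref"]])),
            ce_result("alternative", as.numeric(opts[["cost-alt"]]),
                      as.numeric(opts[["qaly-alt"]])))
  print(e)
  invisible(e)
}

cli_dsa <- function(opts) {
  rc <- cli_build_model(opts)
  tn <- tornado(rc$model, delta = rc$dsa_delta)
  if (is.null(opts$out)) print(tn)
  else utils::write.csv(tn, opts$out, row.names = FALSE)
  invisible(tn)
}

cli_psa <- function(opts) {
  rc <- cli_build_model(opts)
  psa <- simulate(rc$model, nsim = rc$psa_n, seed = rc$seed)
  if (is.null(opts$out)) print(psa)
  else utils::write.csv(psa$draws, opts$out, row.names = FALSE)
  invisible(psa)
}

cli_sweep <- function(opts) {
  rc <- cli_build_model(opts)
  horizons <- if (!is.null(opts$horizons)) {
    as.numeric(strsplit(opts$horizons, ",")[[1L]])
  } else rc$horizons
  sw <- horizon_sweep(rc$model, horizons)
  if (is.null(opts$out)) print(sw)
  else utils::write.csv(sw, opts$out, row.names = FALSE)
  invisible(sw)
}

cli_simulate <- function(opts) {
  inp <- trastuzumab_inputs()
  arm <- opts$arm %||% "control"
  if (!arm %in% names(inp$counts)) stop("unknown arm: ", arm, call. = FALSE)
  comp <- inp$cost_components[[arm]]
  cfg <- cohort_config(arm,
                       n_patients = as.integer(opts$n %||% inp$arm_sizes[[arm]]),
                       matrix = estimate_transition_matrix(inp$counts[[arm]]),
                       follow_up_years = as.integer(opts$years %||%
                                                      inp$follow_up_years),
                       cost_main = comp$main, cost_second = comp$second,
                       second_fraction = comp$second_fraction)
  coh <- simulate_cohort(cfg, seed = as.integer(opts$seed %||% 1L))
  df <- as.data.frame(coh)
  df$cost_at_entry <- coh$costs[match(df$patient_id, unique(df$patient_id))] *
    (df$year == 0)
  if (is.null(opts$out)) utils::write.csv(df, row.names = FALSE, quote = FALSE)
  else utils::write.csv(df, opts$out, row.names = FALSE, quote = FALSE)
  invisible(coh)
}

cli_fixtures <- function(opts) {
  out <- opts$out %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  inp <- trastuzumab_inputs()
  arms <- list()
  for (a in names(inp$counts)) {
    cnt <- inp$counts[[a]]
    df <- data.frame(from_state = rep(rownames(cnt), each = ncol(cnt)),
                     to_state = rep(colnames(cnt), times = nrow(cnt)),
                     count = as.vector(t(unclass(cnt))))
    df <- df[df$from_state != "death", ]
    fn <- paste0(a, "_counts.csv")
    utils::write.csv(df, file.path(out, fn), row.names = FALSE, quote = FALSE)
    if (a != "trastuzumab") {           # config: control + the three subgroups
      arms[[length(arms) + 1L]] <-
        list(name = a, counts = fn, cost = unname(inp$costs[[a]]),
             cost_sd = unname(inp$cost_sd[[a]]),
             n_patients = unname(inp$arm_sizes[[a]]))
    }
  }
  cfg <- list(arms = arms,
              utilities = as.list(inp$utilities$utilities[
                c("stable", "recurrence", "metastasis")]),
              discount = list(cost = inp$discount$cost,
                              qaly = inp$discount$qaly),
              horizon = list(mode = "fixed", n_cycles = 20),
              thresholds = as.list(inp$thresholds),
              psa = list(n = 1000), dsa = list(delta = 0.1),
              horizons = list(5, 10, 15, 20), seed = 1)
  yaml::write_yaml(cfg, file.path(out, "config.yaml"))
  cli_log(opts, "wrote fixtures to ", out)
  invisible(out)
}
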