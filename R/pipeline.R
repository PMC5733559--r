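# Orchestration: full analysis run with logging and provenance, plus a
# subcommand-style command line entry point.

#' Pipeline configuration
#'
#' Input fields accept either file paths (read with the package readers) or
#' in-memory objects (a `"phylo"` tree, community matrix, site table). A run
#' without a tree performs the metrics-free stages only (group comparison,
#' correlation screen). `sr_table` may supply per-plot SR directly (a
#' data.frame with `plot` and `SR`) when no community matrix is available,
#' e.g. for the bundled Tianshan reference table.
#'
#' @param tree,community,sites Paths or objects (each may be `NULL`).
#' @param sr_table Optional data.frame with `plot` and `SR` columns.
#' @param out_dir Output directory; `NULL` suppresses file output.
#' @param n_rand Randomization trials (>= 99; default 999).
#' @param alpha Two-tailed significance level in (0, 0.5).
#' @param null_nri,null_pd Null model per statistic (see [structure_config()]).
#' @param swap_multiplier Swap-chain length multiplier.
#' @param pd_convention `"proportional"` or `"raw"` PD in the metric table.
#' @param cor_method `"pearson"` or `"spearman"` for the correlation screen.
#' @param n_perm Mantel permutations for distance decay.
#' @param seed Master seed.
#' @param verbose Log stage lines to stderr?
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(tree = NULL, community = NULL, sites = NULL,
                            sr_table = NULL, out_dir = NULL,
                            n_rand = 999, alpha = 0.05,
                            null_nri = "independent_swap",
                            null_pd = "richness", swap_multiplier = 10,
                            pd_convention = "proportional",
                            cor_method = "pearson", n_perm = 999,
                            seed = 1, verbose = FALSE) {
  stopifnot(n_rand >= 99, alpha > 0, alpha < 0.5)
  structure(
    list(tree = tree, community = community, sites = sites,
         sr_table = sr_table, out_dir = out_dir, n_rand = n_rand,
         alpha = alpha, null_nri = null_nri, null_pd = null_pd,
         swap_multiplier = swap_multiplier, pd_convention = pd_convention,
         cor_method = cor_method, n_perm = n_perm, seed = as.integer(seed),
         verbose = isTRUE(verbose)),
    class = "pipeline_config"
  )
}

# Tiny rolling hash of a deparsed object, for provenance lines.
config_hash <- function(x) {
  h <- 0
  for (k in utf8ToInt(paste(deparse(x), collapse = ""))) {
    h <- (h * 31 + k) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

load_input <- function(x, reader) {
  if (is.null(x) || !is.character(x)) x else reader(x)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages, each skipped cleanly when its inputs are absent: input validation;
#' per-plot diversity and randomization structure analysis (tree +
#' community); refugial-vs-colonizing Mann-Whitney comparison of SR (sites
#' with group labels); SR-environment correlation screen (sites with the 25
#' environmental columns); PhyloSor distance decay against geographic and
#' environmental distance (tree + community + coordinates). Identical config
#' and seed give byte-identical output files (the run log carries wall-clock
#' lines and is excluded from that guarantee).
#'
#' @param config A [pipeline_config()].
#' @return A list of class `"run_report"` with `metric_table`,
#'   `diagnostics`, `group_test`, `correlation`, `decay`, `provenance`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log_lines <- character(0)
  log_stage <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    paste0(...))
    log_lines <<- c(log_lines, line)
    if (config$verbose) message(line)
  }
  fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  log_stage("load: config hash ", config_hash(config[c(
    "n_rand", "alpha", "null_nri", "null_pd", "pd_convention",
    "cor_method", "n_perm", "seed")]), ", seed ", config$seed)
  tree <- tryCatch(load_input(config$tree, read_newick),
                   error = function(e) fail("load-tree", e))
  comm <- tryCatch(load_input(config$community, read_community_csv),
                   error = function(e) fail("load-community", e))
  sites <- tryCatch(load_input(config$sites, read_site_csv),
                    error = function(e) fail("load-sites", e))
  sr_tab <- tryCatch(load_input(config$sr_table, function(p)
    read.csv(p, stringsAsFactors = FALSE)),
    error = function(e) fail("load-sr-table", e))

  metric_table <- NULL
  diagnostics <- NULL
  group_test <- NULL
  correlation <- NULL
  decay <- NULL
  has_env <- !is.null(sites) && all(env_variable_names() %in% names(sites))

  if (!is.null(comm) && !is.null(tree)) {
    comm <- tryCatch(validate_against_tree(comm, tree, "strict"),
                     error = function(e) fail("validate", e))
    if (!is.null(sites)) {
      tryCatch(check_alignment(comm, sites),
               error = function(e) fail("validate", e))
      comm <- comm[sites$plot, , drop = FALSE]
    }
    log_stage("structure: ", nrow(comm), " plots x ", ncol(comm),
              " species, n_rand ", config$n_rand)
    sc <- structure_config(n_rand = config$n_rand, alpha = config$alpha,
                           null_nri = config$null_nri,
                           null_pd = config$null_pd,
                           swap_multiplier = config$swap_multiplier,
                           pd_convention = config$pd_convention,
                           seed = config$seed)
    sa <- tryCatch(structure_analysis(tree, comm, sc),
                   error = function(e) fail("structure", e))
    metric_table <- sa$metric_table
    diagnostics <- sa$diagnostics
  }

  sr <- if (!is.null(comm)) {
    richness(comm)
  } else if (!is.null(sr_tab)) {
    stats::setNames(sr_tab$SR, sr_tab$plot)
  } else NULL

  if (!is.null(sr) && !is.null(sites) && "group" %in% names(sites)) {
    if (!setequal(names(sr), sites$plot)) fail("group-test",
      simpleError("plot ids differ between SR source and site table"))
    sr_al <- sr[sites$plot]
    log_stage("group-test: ", sum(sites$group == "refugial"), " refugial vs ",
              sum(sites$group == "colonizing"), " colonizing plots")
    group_test <- tryCatch(
      mann_whitney_u(sr_al[sites$group == "refugial"],
                     sr_al[sites$group == "colonizing"]),
      error = function(e) fail("group-test", e))
  }

  if (!is.null(sr) && has_env) {
    log_stage("correlate: 25 environmental variables + refugium indicator")
    correlation <- tryCatch(
      correlation_screen(sr, sites, method = config$cor_method),
      error = function(e) fail("correlate", e))
  }

  if (!is.null(comm) && !is.null(tree) && !is.null(sites) && has_env) {
    log_stage("distance-decay: PhyloSor vs geographic and environmental distance")
    decay <- tryCatch({
      ps <- phylosor_matrix(tree, comm)
      geo <- geographic_distance_matrix(sites)
      env <- environmental_distance(sites)
      distance_decay(ps, geo, env, n_perm = config$n_perm,
                     seed = derive_seed(config$seed, "decay"))
    }, error = function(e) fail("distance-decay", e))
  }

  provenance <- list(
    config = list(n_rand = config$n_rand, alpha = config$alpha,
                  null_nri = config$null_nri, null_pd = config$null_pd,
                  swap_multiplier = config$swap_multiplier,
                  pd_convention = config$pd_convention,
                  cor_method = config$cor_method, n_perm = config$n_perm,
                  seed = config$seed),
    config_hash = config_hash(config[c(
      "n_rand", "alpha", "null_nri", "null_pd", "pd_convention",
      "cor_method", "n_perm", "seed")]),
    package = as.character(packageVersion("phylocomm"))
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    if (!is.null(metric_table)) write_tsv(metric_table,
                                          file.path(od, "metric_table.tsv"))
    if (!is.null(diagnostics)) write_tsv(diagnostics,
                                         file.path(od, "null_diagnostics.tsv"))
    if (!is.null(group_test)) {
      jsonlite::write_json(unclass(group_test),
                           file.path(od, "group_test.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(correlation)) write_tsv(correlation,
                                         file.path(od, "correlation_screen.tsv"))
    if (!is.null(decay)) {
      write_tsv(decay$pairs, file.path(od, "distance_pairs.tsv"))
      jsonlite::write_json(decay$summary, file.path(od, "decay_summary.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(provenance, file.path(od, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_stage("done in ", format(round(
      as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)), " s")
    writeLines(log_lines, file.path(od, "run.log"))
  }

  structure(
    list(metric_table = metric_table, diagnostics = diagnostics,
         group_test = group_test, correlation = correlation, decay = decay,
         provenance = provenance),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  if (!is.null(x$metric_table)) {
    cat("  metric table:", nrow(x$metric_table), "plots\n")
  }
  if (!is.null(x$group_test)) {
    cat(sprintf("  group test: U = %g, p = %.4g\n",
                x$group_test$U, x$group_test$p_value))
  }
  if (!is.null(x$correlation)) {
    cat("  correlation screen:", sum(x$correlation$stars != ""),
        "of", nrow(x$correlation), "variables starred\n")
  }
  if (!is.null(x$decay)) {
    cat(sprintf("  distance decay: Mantel p (geo) = %.3f, (env) = %.3f\n",
                x$decay$summary$geographic$mantel_p,
                x$decay$summary$environmental$mantel_p))
  }
  invisible(x)
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numbers when possible. Command-line flags override file values.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

cli_usage <- function() {
  paste(
    "usage: phylocomm <subcommand> [flags]",
    "subcommands: simulate | metrics | nulltest | group-test | correlate |",
    "             distance-decay | full-run",
    "flags: --tree F --community F --sites F --sr F --out DIR --seed N",
    "       --n-rand N --alpha A --null-model M --pd-convention C",
    "       --scenario S --config FILE --verbose",
    sep = "\n")
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  valued <- c("--tree", "--community", "--sites", "--sr", "--out", "--seed",
              "--n-rand", "--alpha", "--null-model", "--pd-convention",
              "--scenario", "--config")
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--verbose") {
      flags$verbose <- TRUE
      i <- i + 1L
    } else if (a %in% valued) {
      if (i == length(args)) stop("flag ", a, " needs a value")
      flags[[gsub("-", "_", sub("^--", "", a), fixed = TRUE)]] <- args[i + 1L]
      i <- i + 2L
    } else {
      stop("unknown flag: ", a)
    }
  }
  flags
}

#' Command-line entry point
#'
#' Subcommand-style interface over the pipeline. Returns (invisibly) an exit
#' status: 0 on success, 1 on validation/runtime failure, 2 on usage errors
#' (unknown subcommand or flag, missing required flag). Diagnostics go to
#' stderr. Run from a shell as
#' `Rscript -e 'quit(status = phylocomm::phylocomm_cli())'` plus arguments.
#'
#' @param args Character vector of arguments (default: the command line).
#' @return Integer exit status, invisibly.
#' @export
phylocomm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  sub <- if (length(args)) args[1] else ""
  known <- c("simulate", "metrics", "nulltest", "group-test", "correlate",
             "distance-decay", "full-run")
  if (!sub %in% known) {
    message(cli_usage())
    return(invisible(2L))
  }
  flags <- tryCatch(parse_cli_flags(args[-1]), error = function(e) e)
  if (inherits(flags, "error")) {
    message(conditionMessage(flags), "\n", cli_usage())
    return(invisible(2L))
  }
  if (!is.null(flags$config)) {
    fromfile <- tryCatch(read_config_file(flags$config), error = function(e) e)
    if (inherits(fromfile, "error")) {
      message(conditionMessage(fromfile))
      return(invisible(1L))
    }
    for (k in names(fromfile)) {
      if (is.null(flags[[k]])) flags[[k]] <- as.character(fromfile[[k]])
    }
  }
  need <- function(...) {
    missing <- setdiff(c(...), names(flags))
    if (length(missing)) {
      message("missing required flag(s): --",
              paste(gsub("_", "-", missing), collapse = " --"), "\n",
              cli_usage())
      TRUE
    } else FALSE
  }
  seed <- if (is.null(flags$seed)) 1L else as.integer(flags$seed)
  n_rand <- if (is.null(flags$n_rand)) 999 else as.integer(flags$n_rand)
  alpha <- if (is.null(flags$alpha)) 0.05 else as.numeric(flags$alpha)

  status <- tryCatch({
    if (sub == "simulate") {
      if (need("out")) return(invisible(2L))
      scen <- if (is.null(flags$scenario)) "neutral" else flags$scenario
      st <- generate_study(sim_config(seed = seed, scenario = scen))
      write_study(st, flags$out)
      0L
    } else if (sub == "metrics") {
      if (need("tree", "community", "out")) return(invisible(2L))
      tree <- read_newick(flags$tree)
      comm <- validate_against_tree(read_community_csv(flags$community),
                                    tree, "strict")
      dir.create(flags$out, recursive = TRUE, showWarnings = FALSE)
      write_tsv(per_plot_diversity(tree, comm),
                file.path(flags$out, "diversity.tsv"))
      0L
    } else if (sub == "nulltest") {
      if (need("tree", "community", "out")) return(invisible(2L))
      cfg <- pipeline_config(tree = flags$tree, community = flags$community,
                             out_dir = flags$out, n_rand = n_rand,
                             alpha = alpha, seed = seed,
                             verbose = isTRUE(flags$verbose))
      run_full(cfg)
      0L
    } else if (sub == "group-test") {
      if (need("sites", "out") || (is.null(flags$sr) && is.null(flags$community))) {
        if (is.null(flags$sr) && is.null(flags$community)) {
          message("group-test needs --sr or --community\n", cli_usage())
        }
        return(invisible(2L))
      }
      cfg <- pipeline_config(community = flags$community, sites = flags$sites,
                             sr_table = flags$sr, out_dir = flags$out,
                             seed = seed, verbose = isTRUE(flags$verbose))
      run_full(cfg)
      0L
    } else if (sub == "correlate") {
      if (need("community", "sites", "out")) return(invisible(2L))
      cfg <- pipeline_config(community = flags$community, sites = flags$sites,
                             out_dir = flags$out, seed = seed,
                             verbose = isTRUE(flags$verbose))
      run_full(cfg)
      0L
    } else if (sub == "distance-decay" || sub == "full-run") {
      if (need("tree", "community", "sites", "out")) return(invisible(2L))
      cfg <- pipeline_config(
        tree = flags$tree, community = flags$community, sites = flags$sites,
        out_dir = flags$out, n_rand = n_rand, alpha = alpha, seed = seed,
        null_nri = if (is.null(flags$null_model)) "independent_swap" else flags$null_model,
        pd_convention = if (is.null(flags$pd_convention)) "proportional" else flags$pd_convention,
        verbose = isTRUE(flags$verbose))
      run_full(cfg)
      0L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}
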