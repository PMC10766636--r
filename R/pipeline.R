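# One-config orchestration of the full analysis: filter -> diversity ->
# mismatch -> network -> structure -> (optional) ABC, with a JSON + TSV
# report bundle and a run log.

#' Run the full D-loop analysis pipeline
#'
#' Stages run in dependency order; each stage writes its outputs as soon as
#' it completes, so a failure leaves earlier results intact. All
#' randomness is governed by `config$seed`.
#'
#' @param config either a path to a JSON config file or a named list with
#'   entries: `fasta`, `meta` (paths), `group` (structure grouping column,
#'   default "locality"), `exclude_samples` (ids dropped before structure
#'   analyses), `max_missing_frac` (default 0.7), `K` (SAMOVA groups,
#'   default 2), `mu_site`, `seed`, `out_dir`, and optionally `abc` (list:
#'   `sample_sizes`, `n_per_scenario`, `tolerance`, `pop_column`).
#' @return invisible list of stage results; writes `diversity.json`,
#'   `mismatch.tsv`, `network_nodes.tsv`, `network_edges.tsv`,
#'   `structure.json`, `tree.nwk`, optionally `abc.json`, and `run_log.json`
#'   in `out_dir`.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- utils::modifyList(list(group = "locality", max_missing_frac = 0.7,
                                K = 2, mu_site = 3.13e-7, seed = 1,
                                exclude_samples = character(0)),
                           config)
  if (is.null(cfg$fasta) || is.null(cfg$meta) || is.null(cfg$out_dir))
    stop("config needs fasta, meta and out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  log <- list(package_version = as.character(utils::packageVersion("dloopr")),
              seed = cfg$seed,
              config_hash = sum(utils::head(
                utf8ToInt(jsonlite::toJSON(cfg[order(names(cfg))],
                                           auto_unbox = TRUE)), 1e5)),
              started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              stages = character(0))
  results <- list()

  # filter
  aln <- read_alignment(cfg$fasta)
  meta <- read_sample_table(cfg$meta, aln)
  aln_f <- filter_sites(aln, cfg$max_missing_frac)
  removed <- attr(aln_f, "removed_sites")
  jsonlite::write_json(list(n = aln_f$n, L_original = aln$L,
                            L_retained = aln_f$L,
                            removed_sites_1based = as.list(removed + 1)),
                       file.path(cfg$out_dir, "filter.json"),
                       auto_unbox = TRUE, digits = NA)
  log$stages <- c(log$stages, "filter")

  # diversity (monomorphic input: D undefined, recorded as null)
  rates <- rate_constants(L = aln_f$L, mu_site = cfg$mu_site)
  ds <- tryCatch(tajimas_d(aln_f), error = function(e) {
    pd0 <- pairwise_differences(aln_f)
    list(n = aln_f$n, S = segregating_sites(aln_f), k_hat = 0,
         pi_site = nucleotide_diversity(pd0),
         H = haplotype_diversity(collapse_haplotypes(aln_f)),
         tajima_D = NULL, tajima_p = NULL, tajima_p_flag = "undefined")
  })
  jsonlite::write_json(unclass(ds), file.path(cfg$out_dir,
                                              "diversity.json"),
                       auto_unbox = TRUE, digits = NA)
  results$diversity <- ds
  log$stages <- c(log$stages, "diversity")

  # mismatch + expansion dating
  pd <- pairwise_differences(aln_f)
  obs <- mismatch_observed(pd)
  fit <- fit_sudden_expansion(obs)
  mm <- data.frame(differences = as.integer(names(fit$observed)),
                   observed = fit$observed, expected = fit$expected)
  utils::write.table(mm, file.path(cfg$out_dir, "mismatch.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  results$mismatch <- c(fit[c("tau", "theta0", "theta1", "SSD")],
                        expansion_years = expansion_time(fit$tau, rates))
  log$stages <- c(log$stages, "mismatch")

  # network (skipped when fewer than 2 haplotypes)
  ht <- collapse_haplotypes(aln_f)
  write_haplotype_table(ht, file.path(cfg$out_dir, "haplotypes.tsv"))
  if (length(ht$counts) >= 2) {
    net <- build_mj_network(ht)
    write_network_tables(net, file.path(cfg$out_dir, "network_nodes.tsv"),
                         file.path(cfg$out_dir, "network_edges.tsv"),
                         ht = ht, meta = meta)
    results$network <- net
    log$stages <- c(log$stages, "network")
  }

  # structure (after exclusions)
  keep_ids <- setdiff(rownames(aln_f$seqs), cfg$exclude_samples)
  aln_s <- subset_alignment(aln_f, keep_ids)
  meta_s <- meta[meta$sample_id %in% keep_ids, ]
  pdm <- pop_distances(aln_s, meta_s, cfg$group)
  tr <- midpoint_root(nj_tree(pdm))
  ape::write.tree(tr, file.path(cfg$out_dir, "tree.nwk"))
  sam <- samova(aln_s, meta_s, K = cfg$K, group_by = cfg$group,
                seed = cfg$seed)
  jsonlite::write_json(list(n_structure = aln_s$n, K = sam$K,
                            partition = sam$partition,
                            FCT = sam$FCT, FSC = sam$FSC, FST = sam$FST,
                            seed = cfg$seed,
                            net_distance = as.data.frame(pdm$dA)),
                       file.path(cfg$out_dir, "structure.json"),
                       auto_unbox = TRUE, digits = NA)
  results$structure <- list(pop_distances = pdm, tree = tr, samova = sam)
  log$stages <- c(log$stages, "structure")

  # ABC (optional; reduced-scale by default)
  if (!is.null(cfg$abc)) {
    ab <- utils::modifyList(list(n_per_scenario = 1000, tolerance = 0.01,
                                 pop_column = "population",
                                 sample_sizes = NULL), cfg$abc)
    pops_obs <- meta$population[match(rownames(aln_f$seqs),
                                      meta$sample_id)]
    if (is.null(ab$sample_sizes)) {
      tab <- base::table(pops_obs)
      ab$sample_sizes <- stats::setNames(as.integer(tab), names(tab))
    }
    scns <- lapply(1:3, demographic_scenario)
    reft <- build_reference_table(scns, ab$n_per_scenario,
                                  ab$sample_sizes, L = aln_f$L,
                                  seed = cfg$seed)
    obs_ss <- summary_stats(aln_f, pops_obs)
    rej <- abc_reject(obs_ss, reft, ab$tolerance)
    post <- scenario_posterior(reft, rej, obs_ss)
    jsonlite::write_json(list(PP = post$PP, method = post$method,
                              n_retained = post$n_retained,
                              tolerance = ab$tolerance,
                              n_per_scenario = ab$n_per_scenario),
                         file.path(cfg$out_dir, "abc.json"),
                         auto_unbox = TRUE, digits = NA)
    results$abc <- post
    log$stages <- c(log$stages, "abc")
  }

  log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

#' Command-line interface
#'
#' Dispatches the subcommands `run-all`, `diversity`, `mismatch`,
#' `structure` and `synth` from a character vector of arguments
#' (`Rscript -e 'dloopr::dloopr_cli()'` style usage, or via
#' `inst/scripts/dloopr-cli.R`). Options use `--key value` pairs.
#'
#' @param args character vector (default `commandArgs(trailingOnly =
#'   TRUE)`).
#' @return invisibly, the result of the dispatched stage.
#' @export
dloopr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: <run-all|diversity|mismatch|structure|",
                          "synth> [--key value ...]")
  cmd <- args[1]
  kv <- args[-1]
  if (length(kv) %% 2 != 0) stop("options must be --key value pairs")
  opt <- stats::setNames(as.list(kv[c(FALSE, TRUE)]),
                         sub("^--", "", kv[c(TRUE, FALSE)]))
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  chr <- function(x, d) if (is.null(x)) d else x
  out <- switch(cmd,
    "run-all" = run_all(chr(opt$config, stop("--config required"))),
    "filter" = {
      aln <- filter_sites(read_alignment(chr(opt$fasta,
                                             stop("--fasta required"))),
                          num(opt[["max-missing"]], 0.7))
      removed <- attr(aln, "removed_sites")
      cat("retained", aln$L, "sites; removed",
          length(removed), "sites at 1-based positions:",
          paste(removed + 1, collapse = ","), "\n")
      aln
    },
    "network" = {
      aln <- filter_sites(read_alignment(chr(opt$fasta,
                                             stop("--fasta required"))))
      net <- build_mj_network(collapse_haplotypes(aln))
      if (!is.null(opt$out)) {
        dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
        write_network_tables(net, file.path(opt$out, "network_nodes.tsv"),
                             file.path(opt$out, "network_edges.tsv"))
      }
      print(net); net
    },
    "abc-simulate" = {
      sizes <- c(Madagascar = num(opt[["n-madagascar"]], 76),
                 EastAfrica = num(opt[["n-eastafrica"]], 30),
                 WestAsia = num(opt[["n-westasia"]], 50))
      tab <- build_reference_table(lapply(1:3, demographic_scenario),
                                   num(opt$n, 1000) %/% 3, sizes,
                                   seed = num(opt$seed, 1))
      utils::write.table(tab, chr(opt$out, stop("--out required")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      invisible(tab)
    },
    "abc-fit" = {
      tab <- utils::read.table(chr(opt$table, stop("--table required")),
                               header = TRUE, sep = "\t")
      aln <- filter_sites(read_alignment(chr(opt$fasta,
                                             stop("--fasta required"))))
      meta <- read_sample_table(chr(opt$meta, stop("--meta required")),
                                aln)
      pops <- meta$population[match(rownames(aln$seqs), meta$sample_id)]
      obs <- summary_stats(aln, pops)
      rej <- abc_reject(obs, tab, num(opt$tolerance, 0.01))
      post <- scenario_posterior(tab, rej, obs)
      print(post); post
    },
    "diversity" = {
      aln <- filter_sites(read_alignment(chr(opt$fasta,
                                             stop("--fasta required"))))
      meta <- read_sample_table(chr(opt$meta, stop("--meta required")), aln)
      res <- diversity_by_group(aln, meta, chr(opt$group, "population"))
      print(res); res
    },
    "mismatch" = {
      aln <- filter_sites(read_alignment(chr(opt$fasta,
                                             stop("--fasta required"))))
      fit <- fit_sudden_expansion(
        mismatch_observed(pairwise_differences(aln)))
      cat(sprintf("tau=%.4g theta0=%.4g theta1=%.4g SSD=%.3g t=%.0f yr\n",
                  fit$tau, fit$theta0, fit$theta1, fit$SSD,
                  expansion_time(fit$tau, rate_constants(L = aln$L))))
      fit
    },
    "structure" = {
      aln <- filter_sites(read_alignment(chr(opt$fasta,
                                             stop("--fasta required"))))
      meta <- read_sample_table(chr(opt$meta, stop("--meta required")), aln)
      res <- samova(aln, meta, K = num(opt$K, 2),
                    group_by = chr(opt$group, "locality"),
                    seed = num(opt$seed, 1))
      print(res); res
    },
    "synth" = {
      ds <- generate_study_like(study_config(), seed = num(opt$seed, 1))
      write_dataset(ds, chr(opt$out, stop("--out required")))
      ds
    },
    stop("unknown subcommand: ", cmd))
  invisible(out)
}
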