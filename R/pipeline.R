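# Workflow driver: runs the whole analysis (or one branch of it) over a set
# of parasite FASTA files plus one optional host, writing every table as
# TSV/CSV, the plots as PNG, a log, and the resolved configuration for
# provenance. A thin command-line wrapper lives in inst/cli/cubtools.R.

HOST_REQUIRED_INDICES <- c("CAI", "FOP", "MELP", "E", "RCDI", "SiD")

pipeline_subcommands <- function() {
  c("qc", "gc", "dinuc", "indices", "rscu", "adapt", "pca", "plots", "all")
}

#' Run the codon usage analysis pipeline
#'
#' Orchestrates the full workflow: QC (lengths, filtering), nucleotide
#' composition (GC, PR2, neutrality), dinucleotide permutation z-scores,
#' the nine gene-level CUB indices, RSCU tables, host co-adaptation
#' (SiD/RCDI), PCA + clustering, and plots. Each subcommand computes its own
#' prerequisites, so any branch can be run in isolation; `"all"` runs
#' everything. All randomness flows from `seed`. Partial failures (skipped
#' records) never abort a run; a missing host aborts only the branches that
#' cannot be computed without one.
#'
#' @param subcommand One of `"qc"`, `"gc"`, `"dinuc"`, `"indices"`,
#'   `"rscu"`, `"adapt"`, `"pca"`, `"plots"`, `"all"`.
#' @param parasites Character vector of parasite FASTA paths, or a single
#'   directory containing `.fasta`/`.fa` files.
#' @param host Optional path to the single host FASTA.
#' @param sep Header id separator (single character).
#' @param min_aa,max_aa Optional inclusive length bounds in amino acids.
#' @param permutations Dinucleotide permutations (default 100).
#' @param replace Dinucleotide shuffling with replacement?
#' @param models Dinucleotide null models to run.
#' @param seed Integer seed for all randomness.
#' @param exclude_codons Codons excluded from the RSCU matrix.
#' @param k,rank Cluster count and PCA rank for the clustering step.
#' @param out_dir Output directory (created if absent).
#' @param format `"tsv"` or `"csv"`.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_cub_pipeline <- function(subcommand = "all", parasites, host = NULL,
                             sep = "|", min_aa = NULL, max_aa = NULL,
                             permutations = 100L, replace = FALSE,
                             models = c("base", "codon", "syncodon"),
                             seed = 1L,
                             exclude_codons = DEFAULT_EXCLUDE,
                             k = 2L, rank = 2L,
                             out_dir, format = c("tsv", "csv")) {
  subcommand <- match.arg(subcommand, pipeline_subcommands())
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sepc <- if (format == "tsv") "\t" else ","
  ext <- paste0(".", format)
  artifacts <- list()
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, log_con)
    message(msg)
  }
  emit <- function(df, stem) {
    p <- file.path(out_dir, paste0(stem, ext))
    utils::write.table(df, p, sep = sepc, quote = FALSE, row.names = FALSE)
    artifacts[[stem]] <<- p
    p
  }

  if (length(parasites) == 1L && dir.exists(parasites))
    parasites <- sort(list.files(parasites, pattern = "\\.(fa|fasta)$",
                                 full.names = TRUE))
  if (length(parasites) == 0L) stop("no parasite FASTA files found")

  cfg <- list(subcommand = subcommand, parasites = parasites,
              host = host, sep = sep, min_aa = min_aa, max_aa = max_aa,
              permutations = as.integer(permutations), replace = replace,
              models = models, seed = as.integer(seed),
              exclude_codons = exclude_codons, k = as.integer(k),
              rank = as.integer(rank), out_dir = out_dir, format = format)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  artifacts$config <- cfg_path

  say("reading %d parasite file(s)", length(parasites))
  cols <- read_collections(parasites, sep = sep)
  host_col <- if (!is.null(host)) read_host(host, sep = sep) else NULL
  if (!is.null(min_aa) || !is.null(max_aa)) {
    cols <- filter_by_length(cols,
                             if (is.null(min_aa)) 0L else min_aa,
                             if (is.null(max_aa)) .Machine$integer.max
                             else max_aa)
  }
  want <- function(s) subcommand %in% c(s, "all")

  if (want("qc")) {
    emit(qc_report(c(cols, if (!is.null(host_col)) list(host_col))),
         "qc_report")
    emit(length_table(cols), "lengths")
    say("qc: %d retained records", nrow(length_table(cols)))
  }

  gc_tab <- NULL
  if (want("gc") || want("plots")) {
    gc_tab <- gc_table(cols)
    if (want("gc")) {
      emit(gc_tab, "gc_content")
      emit(pr2_table(cols), "pr2_points")
      fits <- do.call(rbind, lapply(split(gc_tab, gc_tab$organism),
        function(g) {
          f <- tryCatch(neutrality_fit(g$gc12, g$gc3),
                        error = function(e) NULL)
          if (is.null(f)) return(NULL)
          data.frame(organism = g$organism[1L], slope = f$slope,
                     intercept = f$intercept, r2 = f$r2, pvalue = f$pvalue,
                     n = f$n, stringsAsFactors = FALSE)
        }))
      if (!is.null(fits)) emit(fits, "neutrality_fits")
      say("gc: composition tables written")
    }
  }

  if (want("dinuc")) {
    for (m in models) {
      emit(dinuc_zscores(cols, model = m, permutations = permutations,
                         replace = replace, seed = seed),
           paste0("dinuc_", m))
    }
    say("dinuc: models %s at %d permutations", paste(models, collapse = ","),
        permutations)
  }

  enc_tab <- NULL
  if (want("indices") || want("plots")) {
    enc_tab <- enc_table(cols)
    if (want("indices")) {
      emit(enc_tab, "enc")
      emit(enc_table(cols, modified = TRUE), "enc_modified")
      emit(milc_table(cols), "milc_self")
      emit(b_table(cols), "b_self")
      emit(mcb_table(cols), "mcb_self")
      if (!is.null(host_col)) {
        emit(milc_table(cols, host_col), "milc_host")
        emit(b_table(cols, host_col), "b_host")
        emit(mcb_table(cols, host_col), "mcb_host")
        emit(cai_table(cols, host_col), "cai")
        emit(fop_table(cols, host_col), "fop")
        emit(melp_table(cols, host_col), "melp")
        emit(e_table(cols, host_col), "e_index")
      } else {
        warning("no host reference: skipped indices that require one: ",
                paste(setdiff(HOST_REQUIRED_INDICES, "SiD"), collapse = ", "),
                call. = FALSE)
        say("indices: host-free only (no --host)")
      }
      say("indices: gene-level tables written")
    }
  }

  if (want("rscu")) {
    emit(rscu_table(cols), "rscu_by_sequence")
    means <- t(vapply(cols, organism_mean_rscu,
                      numeric(length(FAMILY_CODONS))))
    emit(data.frame(organism = rownames(means), means,
                    check.names = FALSE, stringsAsFactors = FALSE),
         "rscu_organism_means")
    if (!is.null(host_col)) {
      hr <- as.data.frame(t(as.numeric(rscu(codon_counts(host_col)))))
      names(hr) <- FAMILY_CODONS
      emit(data.frame(organism = host_col$name, hr, check.names = FALSE,
                      stringsAsFactors = FALSE), "rscu_host")
    }
    say("rscu: codon-level tables written")
  }

  if (want("adapt")) {
    if (is.null(host_col))
      stop("host co-adaptation (SiD, RCDI) requires --host", call. = FALSE)
    emit(sid_table(cols, host_col), "sid")
    emit(rcdi_table(cols, host_col), "rcdi")
    say("adapt: SiD and RCDI written")
  }

  pca_fit <- clus <- NULL
  if (want("pca") || want("plots")) {
    mat <- build_rscu_matrix(cols, host_col, exclude = exclude_codons)
    if (nrow(mat) >= 2L) {
      pca_fit <- pca_rscu(mat)
      if (want("pca")) {
        emit(data.frame(row = rownames(pca_fit$scores), pca_fit$scores,
                        stringsAsFactors = FALSE), "pca_scores")
        emit(data.frame(codon = rownames(pca_fit$loadings),
                        pca_fit$loadings, stringsAsFactors = FALSE),
             "pca_loadings")
        emit(data.frame(component = seq_along(pca_fit$variance_explained),
                        variance_explained = pca_fit$variance_explained),
             "pca_variance")
      }
      if (k <= nrow(mat)) {
        clus <- cluster_on_pca(pca_fit, k = k,
                               rank = min(rank, ncol(pca_fit$scores)),
                               seed = seed)
        if (want("pca"))
          emit(data.frame(row = names(clus$cluster),
                          cluster = unname(clus$cluster),
                          method = clus$method, k = clus$k,
                          rank = clus$rank, stringsAsFactors = FALSE),
               "pca_clusters")
      }
      if (want("pca")) say("pca: %d rows, k = %d", nrow(mat), k)
    } else say("pca: skipped (fewer than 2 rows)")
  }

  if (want("plots")) {
    save_plot <- function(p, stem, width = 7, height = 5) {
      f_png <- file.path(out_dir, paste0(stem, ".png"))
      ggplot2::ggsave(f_png, p, width = width, height = height, dpi = 120)
      f_svg <- file.path(out_dir, paste0(stem, ".svg"))
      ggplot2::ggsave(f_svg, p, device = grDevices::svg,
                      width = width, height = height)
      artifacts[[paste0(stem, "_png")]] <<- f_png
      artifacts[[paste0(stem, "_svg")]] <<- f_svg
    }
    save_plot(plot_qc_boxplot(length_table(cols)), "plot_qc_boxplot")
    save_plot(plot_gc_boxplot(gc_tab), "plot_gc_boxplot")
    save_plot(plot_enc_gc3(enc_tab, gc_tab), "plot_enc_gc3")
    save_plot(plot_enc_gc3(enc_tab, gc_tab, group = TRUE),
              "plot_enc_gc3_group")
    pr2 <- pr2_table(cols)
    save_plot(plot_pr2(pr2), "plot_pr2")
    save_plot(plot_pr2(pr2, group = TRUE), "plot_pr2_group")
    g1 <- gc_tab[gc_tab$organism == gc_tab$organism[1L], ]
    fit <- tryCatch(neutrality_fit(g1$gc12, g1$gc3),
                    error = function(e) NULL)
    if (!is.null(fit))
      save_plot(plot_neutrality(g1, fit), "plot_neutrality")
    hm <- heatmap_matrix(rscu_table(cols), average_per_organism = TRUE)
    save_plot(plot_heatmap(hm), "plot_heatmap")
    if (!is.null(pca_fit)) save_plot(plot_pca(pca_fit, clus), "plot_pca")
    say("plots: figures written")
  }

  say("done: %d artifact(s) in %s", length(artifacts), out_dir)
  invisible(artifacts)
}
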