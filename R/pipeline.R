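#' Parse and validate a run configuration
#'
#' Accepts a named list or a flat `key = value` text file. Unknown keys are
#' rejected; `seed` is mandatory; ranges like `k_range = "2:8"` must be
#' ascending.
#'
#' @param config Named list or path to a key-value file.
#' @return Validated named list of class `ctap_run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    lines <- grep("^\\s*(#|$)", readLines(config), invert = TRUE, value = TRUE)
    kv <- strsplit(lines, "\\s*=\\s*")
    config <- stats::setNames(lapply(kv, function(x) x[2]),
                              vapply(kv, `[`, "", 1))
  }
  known <- c("out_dir", "seed", "n_samples", "cells_min", "cells_max",
             "n_genes", "alpha", "k_range", "n_boot", "min_size",
             "k_neighbors", "steps", "n_perm", "q", "flow_noise_sd",
             "bulk_noise_sd", "assoc_cell_type")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) stop("field 'seed' is mandatory")
  defaults <- list(n_samples = 80L, cells_min = 2000L, cells_max = 3000L,
                   n_genes = 300L, alpha = 200, k_range = "2:8",
                   n_boot = 200L, min_size = 3L, k_neighbors = 30L,
                   steps = 3L, n_perm = 200L, q = 0.05,
                   flow_noise_sd = 0.1, bulk_noise_sd = 0.2,
                   assoc_cell_type = "T")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  num <- c("seed", "n_samples", "cells_min", "cells_max", "n_genes", "alpha",
           "n_boot", "min_size", "k_neighbors", "steps", "n_perm", "q",
           "flow_noise_sd", "bulk_noise_sd")
  for (nm in num) config[[nm]] <- as.numeric(config[[nm]])
  kr <- as.integer(strsplit(as.character(config$k_range), ":")[[1]])
  if (length(kr) != 2L || anyNA(kr) || kr[1] > kr[2])
    stop("invalid field 'k_range': must be an ascending range like 2:8")
  config$k_range <- kr[1]:kr[2]
  structure(config, class = "ctap_run_config")
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate -> stratify -> associate -> classify -> downstream in
#' dependency order, writing TSV/JSON artifacts into `out_dir` and a
#' manifest JSON listing every output with its md5 checksum. Partial
#' outputs are removed on failure. All randomness fans out deterministically
#' from the configured seed.
#'
#' @param config A [run_config()] (list or file path accepted).
#' @return Invisibly, the manifest as a data frame (file, md5).
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  out <- config$out_dir %||% stop("field 'out_dir' is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(file.path(out, written))
    stop("pipeline failed (partial outputs removed): ",
         conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    log_msg <- function(...) message("[ctap] ", ...)
    emit <- function(obj, file) {
      path <- file.path(out, file)
      if (is.data.frame(obj) || is.matrix(obj)) {
        utils::write.table(obj, path, sep = "\t", quote = FALSE,
                           row.names = is.matrix(obj))
      } else {
        jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
      }
      written <<- c(written, file)
    }
    log_msg("simulate: seed ", config$seed)
    sim_cfg <- default_sim_config(
      n_samples = as.integer(config$n_samples),
      cells_per_sample = c(as.integer(config$cells_min),
                           as.integer(config$cells_max)),
      n_genes = as.integer(config$n_genes), alpha = config$alpha,
      flow_noise_sd = config$flow_noise_sd,
      bulk_noise_sd = config$bulk_noise_sd,
      seed = substream_seed(config$seed, "simulate"))
    cohort <- generate_cohort(sim_cfg)
    emit(cohort$cell_table, "cells.tsv")
    emit(cohort$sample_meta, "samples.tsv")

    log_msg("stratify: k_range ", min(config$k_range), ":", max(config$k_range))
    comp <- compute_composition(cohort$cell_table, min_cells = 100L)
    model <- cluster_samples(comp, k_range = config$k_range,
                             n_boot = as.integer(config$n_boot),
                             min_size = as.integer(config$min_size),
                             seed = substream_seed(config$seed, "stratify"))
    labels <- stats::setNames(model$names[model$labels], rownames(comp))
    emit(data.frame(sample_id = names(labels), ctap = labels),
         "ctap_labels.tsv")
    emit(list(k = model$k, names = model$names,
              stability = as.list(model$stability),
              centroids = apply(model$centroids, 1, as.list, simplify = FALSE)),
         "ctap_model.json")

    ct <- config$assoc_cell_type
    log_msg("associate: cell type ", ct)
    sel <- cohort$cell_table$cell_type == ct
    emb <- as.matrix(cohort$cell_table[sel, grep("^emb_", names(cohort$cell_table))])
    rownames(emb) <- cohort$cell_table$cell_id[sel]
    graph <- build_graph(emb, k = as.integer(config$k_neighbors))
    nam <- compute_nam(graph, cohort$cell_table$sample_id[sel],
                       steps = as.integer(config$steps))
    meta <- cohort$sample_meta[match(nam$samples, cohort$sample_meta$sample_id), ]
    covars <- cbind(age = meta$age, sex = as.integer(meta$sex == "F"),
                    log_n_cells = log(as.numeric(table(
                      factor(cohort$cell_table$sample_id[sel], nam$samples)))))
    global_p <- list()
    assoc_rows <- list()
    for (g in model$names) {
      ph <- as.integer(labels[nam$samples] == g)
      res <- associate(nam, ph, covars,
                       n_perm = as.integer(config$n_perm), q = config$q,
                       seed = substream_seed(config$seed, paste0("assoc_", g)))
      global_p[[g]] <- res$global_p
      assoc_rows[[g]] <- data.frame(
        cell_id = names(res$ncorr), ctap = g, ncorr = unname(res$ncorr),
        significant = unname(res$mask))
    }
    emit(do.call(rbind, assoc_rows), "neighbourhood_ncorr.tsv")
    emit(global_p, "neighbourhood_global_p.json")

    log_msg("classify: flow + bulk")
    flow <- simulate_flow_panel(cohort, config$flow_noise_sd,
                                seed = substream_seed(config$seed, "flow"))
    loo <- flow_loo_accuracy(flow[rownames(comp), , drop = FALSE], labels)
    bulk <- mix_pseudobulk(cohort, config$bulk_noise_sd,
                           seed = substream_seed(config$seed, "bulk"))
    sig <- derive_signatures(cohort$counts, cohort$cell_table)
    bulk_pred <- bulk_classify(bulk[, rownames(comp), drop = FALSE], sig, model)
    emit(data.frame(sample_id = bulk_pred$sample_id, bulk_ctap = bulk_pred$ctap,
                    ctap = labels[bulk_pred$sample_id]),
         "bulk_classification.tsv")
    emit(list(flow_loo_accuracy = loo,
              bulk_agreement = mean(bulk_pred$ctap == labels[bulk_pred$sample_id])),
         "classification_metrics.json")

    log_msg("downstream: variance explained")
    meta_all <- cohort$sample_meta[match(rownames(comp),
                                         cohort$sample_meta$sample_id), ]
    ve <- variance_explained(meta_all$CDAI, labels,
                             data.frame(age = meta_all$age,
                                        sex = as.integer(meta_all$sex == "F")))
    emit(list(outcome = "CDAI", fraction = ve$fraction, p = ve$p,
              n = ve$n_used), "variance_explained.json")

    manifest <- data.frame(file = written,
                           md5 = unname(tools::md5sum(file.path(out, written))),
                           stringsAsFactors = FALSE)
    utils::write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_msg("done: ", length(written), " artifacts")
    invisible(manifest)
  }, error = on_fail)
}

#' Validate pipeline input files
#'
#' Checks MatrixMarket headers and dimension agreement, TSV column schemas,
#' the simplex constraint of composition files and the canonical cell-type
#' vocabulary. Never raises on content problems: all failures are returned
#' as a report.
#'
#' @param paths Named list with any of `mtx`, `genes`, `barcodes`, `cells`,
#'   `composition` file paths.
#' @return Data frame report (file, check, message); zero rows when all
#'   checks pass.
#' @export
validate_inputs <- function(paths) {
  failures <- list()
  note <- function(file, check, msg)
    failures[[length(failures) + 1L]] <<-
      data.frame(file = file, check = check, message = msg,
                 stringsAsFactors = FALSE)
  synonyms <- c(fibroblast = "stromal", fibroblasts = "stromal",
                "b" = "B/plasma", "b cell" = "B/plasma", plasma = "B/plasma",
                tcell = "T", "t cell" = "T", mono = "myeloid",
                macrophage = "myeloid", endo = "endothelial",
                "nk cell" = "NK")
  if (!is.null(paths$mtx)) {
    if (!file.exists(paths$mtx)) {
      note(paths$mtx, "exists", "file not found")
    } else {
      header <- readLines(paths$mtx, n = 1L)
      if (!grepl("^%%MatrixMarket matrix coordinate", header)) {
        note(paths$mtx, "mtx_header", paste("malformed header:", header))
      } else {
        m <- Matrix::readMM(paths$mtx)
        if (!is.null(paths$genes) && file.exists(paths$genes) &&
            length(readLines(paths$genes)) != nrow(m))
          note(paths$genes, "mtx_dims", "gene count differs from matrix rows")
        if (!is.null(paths$barcodes) && file.exists(paths$barcodes) &&
            length(readLines(paths$barcodes)) != ncol(m))
          note(paths$barcodes, "mtx_dims",
               "barcode count differs from matrix columns")
      }
    }
  }
  if (!is.null(paths$cells)) {
    cells <- try(utils::read.table(paths$cells, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE), silent = TRUE)
    if (inherits(cells, "try-error")) {
      note(paths$cells, "tsv", "unreadable TSV")
    } else {
      need <- c("cell_id", "sample_id", "cell_type")
      miss <- setdiff(need, names(cells))
      if (length(miss))
        note(paths$cells, "schema",
             paste("missing column(s):", paste(miss, collapse = ", ")))
      if ("cell_type" %in% names(cells)) {
        bad <- setdiff(unique(cells$cell_type), canonical_types())
        for (b in bad) {
          sug <- synonyms[tolower(b)]
          note(paths$cells, "cell_type_vocabulary",
               paste0("'", b, "' is not canonical",
                      if (!is.na(sug)) paste0("; did you mean '", sug, "'?")))
        }
      }
    }
  }
  if (!is.null(paths$composition)) {
    comp <- try(utils::read.table(paths$composition, sep = "\t", header = TRUE,
                                  row.names = 1, check.names = FALSE),
                silent = TRUE)
    if (inherits(comp, "try-error")) {
      note(paths$composition, "tsv", "unreadable TSV")
    } else {
      rs <- rowSums(as.matrix(comp))
      bad <- which(abs(rs - 1) > 1e-6)
      for (i in bad)
        note(paths$composition, "simplex",
             sprintf("row '%s' sums to %.4f, not 1", rownames(comp)[i], rs[i]))
      if (any(as.matrix(comp) < 0))
        note(paths$composition, "simplex", "negative proportions present")
    }
  }
  if (!length(failures))
    return(data.frame(file = character(), check = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, failures)
}

#' Bundled illustrative CTAP transition fixture
#'
#' A deterministic set of 45 baseline/follow-up CTAP label pairs across two
#' biologic treatment arms (29 tocilizumab, 16 rituximab) in which 30 pairs
#' change CTAP (20 and 10 per arm) and 16 of the changed pairs end at
#' CTAP-F. Used to exercise [transition_summary()] arithmetic.
#'
#' @return List with `t0`, `t1` (named label vectors) and `arm`.
#' @export
example_transition_pairs <- function() {
  ctaps <- c("EFM", "F", "TF", "TB", "TM", "M")
  ids <- sprintf("P%02d", 1:45)
  arm <- stats::setNames(rep(c("tocilizumab", "rituximab"), c(29, 16)), ids)
  t0 <- stats::setNames(rep_len(ctaps, 45), ids)
  t1 <- t0
  # changed pairs: first 20 tocilizumab ids, first 10 rituximab ids
  changed <- c(ids[1:20], ids[30:39])
  # 16 of the changed pairs end at CTAP-F (baseline not F), the rest move
  # to the next CTAP in the cycle (skipping their own label and F)
  to_f <- changed[t0[changed] != "F"][1:16]
  t1[to_f] <- "F"
  rest <- setdiff(changed, to_f)
  t1[rest] <- vapply(rest, function(id) {
    opts <- setdiff(ctaps, c(t0[id], "F"))
    opts[(match(id, ids) %% length(opts)) + 1L]
  }, character(1))
  stopifnot(sum(t1 != t0) == 30L, sum(t1[t1 != t0] == "F") == 16L)
  list(t0 = t0, t1 = t1, arm = arm)
}
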