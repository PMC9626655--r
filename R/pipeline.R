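# Pipeline orchestration: synthetic or user-supplied time-course data, run
# end-to-end, and collect a results bundle mirroring the analysis outputs
# (group maps, connectivity, states, transitions, statistics, manifest).

#' Read a network time-course table
#'
#' Delimited text, T rows x n networks, optional header line and optional
#' `# TR=<seconds>` comment. Non-numeric cells and constant columns are
#' errors.
#'
#' @param path file path.
#' @param format `"tsv"` or `"csv"`.
#' @param TR sampling interval in seconds; overridden by a `# TR=` comment.
#' @return T x n numeric matrix with a `TR` attribute.
#' @export
load_time_courses <- function(path, format = c("tsv", "csv"), TR = NA_real_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sep <- if (format == "tsv") "\t" else ","
  lines <- readLines(path)
  tr_line <- grep("^#\\s*TR\\s*=", lines, value = TRUE)
  if (length(tr_line)) {
    TR <- as.numeric(sub("^#\\s*TR\\s*=\\s*", "", tr_line[1]))
  }
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  first <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  body <- lines[if (has_header) -1L else TRUE]
  cells <- strsplit(body, sep, fixed = TRUE)
  ncols <- length(cells[[1]])
  mat <- matrix(NA_real_, length(cells), ncols)
  for (i in seq_along(cells)) {
    if (length(cells[[i]]) != ncols) {
      stop(sprintf("row %d has %d cells, expected %d",
                   i, length(cells[[i]]), ncols))
    }
    vals <- suppressWarnings(as.numeric(cells[[i]]))
    if (any(is.na(vals))) {
      stop(sprintf("non-numeric cell at row %d, column %d",
                   i, which(is.na(vals))[1]))
    }
    mat[i, ] <- vals
  }
  if (has_header) colnames(mat) <- first
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1]
    nm <- if (!is.null(colnames(mat))) colnames(mat)[bad] else bad
    stop(sprintf("constant column: %s", nm))
  }
  attr(mat, "TR") <- TR
  mat
}

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate a cohort) or `"timecourses"`
#'   (pre-extracted network time courses; `sessions` must be supplied).
#' @param cohort a [cohort_config()] (synthetic mode).
#' @param sessions timecourse mode: data.frame with columns `path`,
#'   `subject`, `session` (session 1 = before, 2 = after), `format`.
#' @param W,step sliding-window width and step in samples.
#' @param TR sampling interval in seconds.
#' @param scenarios which clustering scenarios to run, a subset of
#'   `c("pooled", "pre", "post")`.
#' @param apc affinity-propagation settings (preference, damping, max_iter,
#'   conv_window). State extraction defaults to the conservative `"min"`
#'   preference; see [build_similarity()].
#' @param stats_opts statistics settings (fisher_z, q_level).
#' @param max_cluster_points cap on points clustered at the individual level
#'   (windows are subsampled evenly beyond it).
#' @param n_comp number of group components; `NULL` uses the planted source
#'   count (synthetic) or an MDL estimate.
#' @param gica a [gica_params()].
#' @param seed master seed for all stage substreams.
#' @param output_dir optional directory; when set the bundle is written out.
#' @param verbose print per-stage progress.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "timecourses"),
                            cohort = cohort_config(),
                            sessions = NULL,
                            W = 20L, step = 1L, TR = 2,
                            scenarios = c("pooled", "pre", "post"),
                            apc = list(preference = "min", damping = 0.9,
                                       max_iter = 1000L, conv_window = 50L),
                            stats_opts = list(fisher_z = TRUE,
                                              q_level = 0.05),
                            max_cluster_points = 600L,
                            n_comp = NULL,
                            gica = gica_params(),
                            seed = 1L,
                            output_dir = NULL,
                            verbose = FALSE) {
  mode <- match.arg(mode)
  scenarios <- match.arg(scenarios, c("pooled", "pre", "post"),
                         several.ok = TRUE)
  if (mode == "timecourses") {
    if (is.null(sessions) || !all(c("path", "subject", "session") %in%
                                  names(sessions))) {
      stop("timecourse mode needs a sessions table with path/subject/session")
    }
    missing <- !file.exists(sessions$path)
    if (any(missing)) {
      stop(sprintf("missing time-course file: %s",
                   sessions$path[missing][1]))
    }
  }
  structure(list(mode = mode, cohort = cohort, sessions = sessions,
                 W = as.integer(W), step = as.integer(step), TR = TR,
                 scenarios = scenarios, apc = apc, stats_opts = stats_opts,
                 max_cluster_points = as.integer(max_cluster_points),
                 n_comp = n_comp, gica = gica, seed = as.integer(seed),
                 output_dir = output_dir, verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

pipe_log <- function(cfg, fmt, ...) {
  if (cfg$verbose) message(sprintf(paste0("[gicadfc] ", fmt), ...))
}

edge_names <- function(n) {
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  sprintf("%d-%d", pairs[, 1], pairs[, 2])
}

# Cluster one scenario's DFC vector rows and derive occupancy + per-group
# window-label transition matrices.
run_state_scenario <- function(rows, group_mask, seq_id, cfg, seed) {
  model <- build_similarity(rows, preference = cfg$apc$preference,
                            damping = cfg$apc$damping,
                            max_iter = cfg$apc$max_iter,
                            conv_window = cfg$apc$conv_window)
  res <- affinity_propagation(model, seed = seed)
  occ <- state_occupancy(res, group_mask, vectors = rows)
  trans <- lapply(split(seq_along(group_mask), group_mask), function(ii) {
    seqs <- split(occ$labels[ii], seq_id[ii])
    seqs <- seqs[vapply(seqs, length, integer(1)) >= 2]
    if (!length(seqs)) return(NULL)
    estimate_transition_matrix(seqs, n_states = occ$n_states)
  })
  list(apc = res, occupancy = occ, transitions = trans)
}

#' Run the full analysis pipeline
#'
#' Synthetic mode: cohort generation, component-order estimation, subject
#' ICA, intrinsic-reference extraction, constrained group ICA, dual
#' regression, static and sliding-window connectivity at the group and
#' individual levels, affinity-propagation state extraction for the
#' requested scenarios, Markov transition estimation, and paired
#' before/after statistics. Timecourse mode skips the decomposition stages.
#' Deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @return object of class `results_bundle` (a named list; see the fields in
#'   the vignette), with a `manifest` recording config hash, seed, and
#'   package version.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  t0 <- Sys.time()
  cohort <- NULL
  ground_truth <- NULL
  decomposition <- NULL
  if (cfg$mode == "synthetic") {
    pipe_log(cfg, "generating cohort (%d subjects x %d sessions, V=%d)",
             cfg$cohort$n_subjects, cfg$cohort$n_sessions, cfg$cohort$V)
    cohort <- generate_cohort(cfg$cohort)
    ground_truth <- cohort$ground_truth
    tcs_list <- decompose_cohort(cohort, cfg)
    decomposition <- tcs_list$decomposition
    tcs <- tcs_list$time_courses
    subject <- ground_truth$subject
    session <- ground_truth$session
  } else {
    pipe_log(cfg, "loading %d time-course tables", nrow(cfg$sessions))
    fmt <- if (!is.null(cfg$sessions$format)) {
      as.character(cfg$sessions$format)
    } else {
      rep("tsv", nrow(cfg$sessions))
    }
    tcs <- lapply(seq_len(nrow(cfg$sessions)), function(i) {
      load_time_courses(cfg$sessions$path[i], fmt[i], TR = cfg$TR)
    })
    subject <- cfg$sessions$subject
    session <- cfg$sessions$session
  }
  n_net <- ncol(tcs[[1]])
  edges <- edge_names(n_net)
  tcs <- lapply(tcs, scale_cols)

  # --- connectivity ---------------------------------------------------
  pipe_log(cfg, "connectivity: SFC and DFC (W=%d, step=%d)", cfg$W, cfg$step)
  sfc <- lapply(tcs, static_fc)
  sfc_edges <- do.call(rbind, lapply(sfc, vectorize_dfc))
  colnames(sfc_edges) <- edges
  dfcvs_ind <- lapply(tcs, function(tc) {
    assemble_dfc_vector_set(sliding_window_dfc(tc, cfg$W, cfg$step),
                            W = cfg$W, step = cfg$step, TR = cfg$TR)
  })
  group_tc <- lapply(sort(unique(session)), function(s) {
    Reduce(`+`, tcs[session == s]) / sum(session == s)
  })
  group_dfcvs <- lapply(group_tc, function(tc) {
    assemble_dfc_vector_set(sliding_window_dfc(tc, cfg$W, cfg$step),
                            W = cfg$W, step = cfg$step, TR = cfg$TR)
  })
  group_sfc <- lapply(group_tc, static_fc)

  # --- states + transitions -------------------------------------------
  pipe_log(cfg, "state extraction: scenarios %s",
           paste(cfg$scenarios, collapse = "/"))
  has_two <- length(unique(session)) >= 2
  states_group <- list()
  states_individual <- list()
  for (sc in cfg$scenarios) {
    if (!has_two && sc != "pre") next
    keep_sessions <- switch(sc, pooled = c(1, 2), pre = 1, post = 2)
    gsel <- which(seq_along(group_dfcvs) %in% keep_sessions)
    rows <- do.call(rbind, group_dfcvs[gsel])
    mask <- rep(c("pre", "post")[gsel],
                vapply(group_dfcvs[gsel], nrow, integer(1)))
    seq_id <- rep(gsel, vapply(group_dfcvs[gsel], nrow, integer(1)))
    states_group[[sc]] <- run_state_scenario(
      rows, mask, seq_id, cfg, child_seed(cfg$seed, 501))
    isel <- which(session %in% keep_sessions)
    irows <- do.call(rbind, dfcvs_ind[isel])
    imask <- rep(c("pre", "post")[session[isel]],
                 each = nrow(dfcvs_ind[[1]]))
    iseq <- rep(isel, each = nrow(dfcvs_ind[[1]]))
    if (nrow(irows) > cfg$max_cluster_points) {
      keep <- seq(1, nrow(irows),
                  length.out = cfg$max_cluster_points)
      keep <- unique(round(keep))
      irows <- irows[keep, , drop = FALSE]
      imask <- imask[keep]
      iseq <- iseq[keep]
    }
    states_individual[[sc]] <- run_state_scenario(
      irows, imask, iseq, cfg, child_seed(cfg$seed, 601))
  }

  # --- statistics -----------------------------------------------------
  stats_tables <- list()
  if (has_two) {
    pipe_log(cfg, "paired statistics")
    pre_subj <- subject[session == 1]
    post_subj <- subject[session == 2]
    common <- intersect(pre_subj, post_subj)
    pre_rows <- match(common, pre_subj)
    post_rows <- match(common, post_subj)
    stats_tables$sfc_individual <- edgewise_group_comparison(
      sfc_edges[session == 1, , drop = FALSE][pre_rows, , drop = FALSE],
      sfc_edges[session == 2, , drop = FALSE][post_rows, , drop = FALSE],
      level = "individual", fisher_z = cfg$stats_opts$fisher_z,
      q_level = cfg$stats_opts$q_level)
    stats_tables$dfc_group <- edgewise_group_comparison(
      group_dfcvs[[1]], group_dfcvs[[2]],
      level = "group", fisher_z = cfg$stats_opts$fisher_z,
      q_level = cfg$stats_opts$q_level)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gicadfc")),
    seed = cfg$seed,
    mode = cfg$mode,
    W = cfg$W, step = cfg$step, TR = cfg$TR,
    n_sessions_analyzed = length(tcs),
    config_hash = fnv1a(paste(deparse(cfg[setdiff(names(cfg),
                                                  c("output_dir",
                                                    "verbose"))]),
                              collapse = "")),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  bundle <- structure(list(
    config = cfg, manifest = manifest,
    cohort = cohort, ground_truth = ground_truth,
    decomposition = decomposition,
    time_courses = tcs, subject = subject, session = session,
    sfc = sfc, sfc_edges = sfc_edges, group_sfc = group_sfc,
    dfcvs_individual = dfcvs_ind, group_dfcvs = group_dfcvs,
    states_group = states_group, states_individual = states_individual,
    stats = stats_tables), class = "results_bundle")
  if (!is.null(cfg$output_dir)) write_results_bundle(bundle, cfg$output_dir)
  bundle
}

# Subject-level decomposition through dual regression (synthetic mode).
decompose_cohort <- function(cohort, cfg) {
  gt <- cohort$ground_truth
  n_src <- nrow(gt$source_maps)
  n_comp <- if (!is.null(cfg$n_comp)) {
    cfg$n_comp
  } else {
    est <- estimate_num_components(cohort$sessions[[1]]$data)
    if (est < 2 || est > nrow(cohort$sessions[[1]]$data) / 2) n_src else est
  }
  pipe_log(cfg, "subject ICA on %d sessions (n_comp=%d)",
           length(cohort$sessions), n_comp)
  decomps <- lapply(seq_along(cohort$sessions), function(i) {
    fit_subject_ica(cohort$sessions[[i]]$data, n_comp,
                    seed = child_seed(cfg$seed, 100 + i))
  })
  pipe_log(cfg, "intrinsic references + constrained group ICA")
  refs <- lapply(seq_len(n_src), function(k) {
    sel <- select_components_of_interest(decomps, gt$source_maps[k, ])
    if (!nrow(sel$matched_maps)) {
      stop(sprintf("no subject component matched planted source %d", k))
    }
    extract_intrinsic_reference(sel$matched_maps)$reference
  })
  X_group <- do.call(rbind, lapply(cohort$sessions, function(ss) {
    Xc <- ss$data - rowMeans(ss$data)
    Xc / stats::sd(as.vector(Xc))
  }))
  gica <- fit_constrained_group_ica(X_group, refs, params = cfg$gica,
                                    n_whiten = max(n_comp,
                                                   length(refs)))
  pipe_log(cfg, "dual regression")
  dr <- lapply(cohort$sessions, function(ss) dual_regress(ss$data, gica$S))
  list(decomposition = list(subject = decomps, references = refs,
                            group = gica, dual = dr),
       time_courses = lapply(dr, `[[`, "time_courses"))
}

#' Write a results bundle to a directory
#'
#' Connectivity tables, DFC vector sets, state labels and occupancy,
#' transition matrices, statistics tables, and a JSON manifest, all as
#' delimited text.
#'
#' @param bundle a `results_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_results_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(x, name) {
    utils::write.table(x, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wtsv(bundle$sfc_edges, "sfc_edges.tsv")
  for (s in seq_along(bundle$group_dfcvs)) {
    wtsv(bundle$group_dfcvs[[s]], sprintf("group_dfcvs_session%d.tsv", s))
  }
  for (nm in names(bundle$stats)) {
    wtsv(bundle$stats[[nm]], sprintf("stats_%s.tsv", nm))
  }
  for (lvl in c("states_group", "states_individual")) {
    for (sc in names(bundle[[lvl]])) {
      st <- bundle[[lvl]][[sc]]
      wtsv(data.frame(window = seq_along(st$occupancy$labels),
                      state = st$occupancy$labels),
           sprintf("%s_%s_labels.tsv", lvl, sc))
      wtsv(cbind(state = rownames(st$occupancy$counts),
                 as.data.frame(st$occupancy$counts)),
           sprintf("%s_%s_counts.tsv", lvl, sc))
      for (g in names(st$transitions)) {
        if (is.null(st$transitions[[g]])) next
        wtsv(st$transitions[[g]]$P,
             sprintf("%s_%s_transitions_%s.tsv", lvl, sc, g))
      }
    }
  }
  if (!is.null(bundle$decomposition)) {
    wtsv(bundle$decomposition$group$S, "group_maps.tsv")
  }
  jsonlite::write_json(bundle$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
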