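# Protocol enumeration and orchestration over a pluggable refinement
# backend. The built-in toy backend is a restraint-only gradient-descent
# minimizer: it lets the whole pipeline run on synthetic structures, and its
# "pseudo-R" statistic is a monotone transform of the restraint residual,
# NOT a crystallographic R factor.

PROTOCOL_KINDS <- c(paste0("ERH_top", 1:3), paste0("ERH_distant", 1:3),
                    "ERH_all", "ERB", "JELLY")

new_protocol <- function(kind, homologues = character(), cycles = 20) {
  stages <- if (kind == "JELLY") {
    list(list(restraints = "jelly", cycles = cycles))
  } else if (kind == "ERB") {
    list(list(restraints = "hbond", cycles = cycles),
         list(restraints = "jelly", cycles = cycles))
  } else {
    list(list(restraints = "homologue", cycles = cycles),
         list(restraints = "jelly", cycles = cycles))
  }
  structure(list(id = kind, kind = kind, homologues = homologues,
                 stages = stages), class = "refine_protocol")
}

#' Enumerate candidate refinement protocols
#'
#' With at least three ranked homologues the full grid is produced: external
#' restraints from the one, two and three best-ranked homologues
#' (\code{ERH_top1..3}), from the one, two and three homologues with the
#' largest global r.m.s.d. (\code{ERH_distant1..3}), from all available
#' homologues (\code{ERH_all}), plus the two homologue-free protocols:
#' hydrogen-bond restraints (\code{ERB}) and jelly-body restraints
#' (\code{JELLY}). Protocols whose homologue sets coincide (as unordered
#' sets) are deduplicated, keeping the first; with no homologues only
#' \code{ERB} and \code{JELLY} remain. Every homologue-using protocol runs
#' its external-restraint stage followed by a jelly-body relaxation stage;
#' \code{JELLY} is a single round.
#'
#' @param ranked_homologues List of \code{"homologue_assessment"} objects
#'   already filtered and ranked best-first (see [rank_homologues()]).
#' @param max_homologues Largest homologue-subset size K (default 3).
#' @param cycles Minimization cycles per stage for the toy backend.
#' @return List of \code{"refine_protocol"} objects.
#' @export
enumerate_protocols <- function(ranked_homologues, max_homologues = 3,
                                cycles = 20) {
  ids <- vapply(ranked_homologues, `[[`, "", "ref_id")
  distant <- vapply(order_by_global_rmsd(ranked_homologues), `[[`, "", "ref_id")
  n <- length(ids)
  cand <- list()
  if (n > 0) {
    K <- min(max_homologues, n)
    for (k in seq_len(K))
      cand[[length(cand) + 1]] <- new_protocol(paste0("ERH_top", k),
                                               ids[seq_len(k)], cycles)
    for (k in seq_len(K))
      cand[[length(cand) + 1]] <- new_protocol(paste0("ERH_distant", k),
                                               distant[seq_len(k)], cycles)
    cand[[length(cand) + 1]] <- new_protocol("ERH_all", ids, cycles)
  }
  cand[[length(cand) + 1]] <- new_protocol("ERB", cycles = cycles)
  cand[[length(cand) + 1]] <- new_protocol("JELLY", cycles = cycles)
  seen <- character(0)
  out <- list()
  for (p in cand) {
    key <- if (p$kind %in% c("ERB", "JELLY")) p$kind else
      paste(sort(p$homologues), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1]] <- p
  }
  out
}

## ---- toy restrained minimizer -----------------------------------------

#' Toy restraint-only minimizer
#'
#' Gradient descent with backtracking line search on the objective
#' \deqn{E = \sum_{groups} \min_{alternatives} ((d - d_{target})/\sigma)^2,}
#' where within each alternative group the restraint whose objective is
#' closest to the current interatomic distance is the active one on every
#' cycle (so with restraints from several homologues the structure is pulled
#' toward whichever reference it already most resembles, pair by pair). The
#' reported pseudo-R statistic, \code{100 * s / (1 + s)} with
#' \code{s = sqrt(E / n_groups)}, is a monotone transform of the residual
#' used only to compare protocol outcomes of this toy backend; it is not a
#' crystallographic R factor.
#'
#' @param model A \code{"pdb_structure"}.
#' @param restraint_set A \code{"restraint_set"}; every referenced atom must
#'   exist in \code{model}. An empty set returns the model unchanged.
#' @param cycles Maximum descent cycles (0 = evaluate only).
#' @return An object of class \code{"refinement_result"}: list with
#'   \code{structure} (moved model), \code{r_work}, \code{r_free},
#'   \code{energy}, \code{n_groups} and the per-cycle energy \code{trace}.
#' @export
toy_refine <- function(model, restraint_set, cycles = 20) {
  check_structure(model)
  stopifnot(inherits(restraint_set, "restraint_set"))
  df <- restraint_set$restraints
  if (nrow(df) == 0)
    return(structure(list(structure = model, r_work = 0, r_free = 0,
                          energy = 0, n_groups = 0, trace = numeric(0)),
                     class = "refinement_result"))
  at <- model$atoms
  akey <- paste(at$chain, at$resno, at$ins, at$elety, sep = "\r")
  i1 <- match(paste(df$chain1, df$resi1, df$ins1, df$atom1, sep = "\r"), akey)
  i2 <- match(paste(df$chain2, df$resi2, df$ins2, df$atom2, sep = "\r"), akey)
  if (anyNA(i1) || anyNA(i2))
    stop_lrr("input_error", "restraint references atom(s) absent from model '",
             model$id, "'")
  X <- coords_matrix(model)
  w <- 1 / df$sigma^2
  tgt <- df$target
  grp <- df$group
  n_groups <- length(unique(grp))
  energy_and_active <- function(X) {
    dv <- X[i1, , drop = FALSE] - X[i2, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    # active alternative per group: objective closest to current distance
    gap <- abs(d - tgt)
    ord <- order(grp, gap)
    active <- ord[!duplicated(grp[ord])]
    list(E = sum(w[active] * (d[active] - tgt[active])^2),
         active = active, d = d, dv = dv)
  }
  st <- energy_and_active(X)
  trace <- numeric(0)
  # each cycle: freeze the active alternative of every group, take a few
  # quasi-Newton descent steps on the resulting smooth objective, then
  # re-select the active alternatives; E never increases across cycles
  for (cyc in seq_len(cycles)) {
    active <- st$active
    e_fixed <- function(xv) {
      Xn <- matrix(xv, ncol = 3)
      dv <- Xn[i1[active], , drop = FALSE] - Xn[i2[active], , drop = FALSE]
      d <- sqrt(rowSums(dv^2))
      sum(w[active] * (d - tgt[active])^2)
    }
    g_fixed <- function(xv) {
      Xn <- matrix(xv, ncol = 3)
      dv <- Xn[i1[active], , drop = FALSE] - Xn[i2[active], , drop = FALSE]
      d <- pmax(sqrt(rowSums(dv^2)), 1e-9)
      coef <- 2 * w[active] * (d - tgt[active]) / d
      G <- matrix(0, nrow(Xn), 3)
      agg <- rowsum(rbind(dv * coef, -dv * coef), c(i1[active], i2[active]))
      G[as.integer(rownames(agg)), ] <- agg
      as.vector(G)
    }
    opt <- stats::optim(as.vector(X), e_fixed, g_fixed, method = "L-BFGS-B",
                        control = list(maxit = 10))
    Xn <- matrix(opt$par, ncol = 3)
    stn <- energy_and_active(Xn)
    if (stn$E <= st$E + 1e-9) {
      X <- Xn
      st <- stn
    }
    trace <- c(trace, st$E)
    if (st$E < 1e-12) break
  }
  s <- sqrt(st$E / n_groups)
  r <- 100 * s / (1 + s)
  structure(list(structure = set_coords(model, X), r_work = r, r_free = r,
                 energy = st$E, n_groups = n_groups, trace = trace),
            class = "refinement_result")
}

#' Built-in toy refinement backend
#'
#' The pluggable-backend contract: a function taking the current model, a
#' restraint set and a list of stage options, returning the refined model
#' and its statistics. This implementation wraps [toy_refine()]; the
#' crystallographic pass-through options (\code{twin}, \code{scaling},
#' \code{mr_mode}) are accepted and ignored, and no MolProbity percentile is
#' produced, so downstream selection falls back to R_free.
#'
#' @param model A \code{"pdb_structure"}.
#' @param restraint_set A \code{"restraint_set"}.
#' @param options List: \code{cycles} (default 20) plus pass-through flags.
#' @return List with \code{model}, \code{r_work}, \code{r_free} and
#'   \code{mp_percentile} (NA for this backend).
#' @export
toy_backend <- function(model, restraint_set, options = list()) {
  res <- toy_refine(model, restraint_set, cycles = options$cycles %||% 20)
  list(model = res$structure, r_work = res$r_work, r_free = res$r_free,
       mp_percentile = NA_real_)
}

## ---- protocol execution ------------------------------------------------

# build the restraint set for one stage of a protocol against `model`;
# refs: named list of as_restraint_ref() entries keyed by homologue id
stage_restraints <- function(stage, model, protocol, refs, config) {
  switch(stage$restraints,
    homologue = {
      use <- refs[protocol$homologues]
      hr <- generate_homologue_restraints(model, use, config)
      # chains with no contributing homologue keep their backbone together
      # with hydrogen-bond restraints instead
      covered <- unique(vapply(use, function(r)
        r$target_chain %||% chain_ids(model)[1], ""))
      uncovered <- setdiff(chain_ids(model), covered)
      if (length(uncovered)) {
        hb <- generate_hbond_restraints(model, config)
        hbdf <- hb$restraints
        hbdf <- hbdf[hbdf$chain1 %in% uncovered & hbdf$chain2 %in% uncovered, ,
                     drop = FALSE]
        hb$restraints <- hbdf
        combine_restraint_sets(list(hr, hb), model$id)
      } else hr
    },
    hbond = generate_hbond_restraints(model, config),
    jelly = generate_jelly_restraints(model, config),
    stop_lrr("input_error", "unknown stage restraint kind '", stage$restraints, "'"))
}

#' Run one refinement protocol
#'
#' Executes the protocol's stages in order through the backend: the external
#' stage first (homologue or hydrogen-bond restraints generated against the
#' current model), then — for two-stage protocols — a jelly-body stage whose
#' self-restraints are regenerated on the stage-one output so the structure
#' relaxes about its new conformation. In molecular-replacement mode a
#' jelly-body relaxation stage is prepended, running 100 cycles, or 200 when
#' the starting pseudo-R_free exceeds 40 percent.
#'
#' @param protocol A \code{"refine_protocol"} from [enumerate_protocols()].
#' @param target A \code{"pdb_structure"} to refine.
#' @param refs Named list of reference entries (see
#'   [generate_homologue_restraints()]), keyed by homologue id.
#' @param backend Backend function (see [toy_backend()]).
#' @param config A [restraint_config()].
#' @param options List: \code{mr_mode} (default FALSE), \code{twin},
#'   \code{scaling} pass-throughs.
#' @return A list (\code{protocol}, \code{r_work}, \code{r_free},
#'   \code{mp_percentile}, \code{model}, \code{stages_run}).
#' @export
run_protocol <- function(protocol, target, refs = list(),
                         backend = toy_backend, config = restraint_config(),
                         options = list()) {
  stopifnot(inherits(protocol, "refine_protocol"))
  model <- target
  stages <- protocol$stages
  if (isTRUE(options$mr_mode)) {
    start <- backend(model, stage_restraints(stages[[1]], model, protocol,
                                             refs, config),
                     c(options, list(cycles = 0)))
    mr_cycles <- if (start$r_free > 40) 200 else 100
    stages <- c(list(list(restraints = "jelly", cycles = mr_cycles)), stages)
  }
  stats <- NULL
  for (stage in stages) {
    rs <- stage_restraints(stage, model, protocol, refs, config)
    stats <- backend(model, rs, c(options, list(cycles = stage$cycles)))
    model <- stats$model
  }
  list(protocol = protocol$id, r_work = stats$r_work, r_free = stats$r_free,
       mp_percentile = stats$mp_percentile %||% NA_real_, model = model,
       stages_run = length(stages))
}

## ---- full pipeline -----------------------------------------------------

#' Run the complete low-resolution refinement pipeline
#'
#' Reads the target model and any homologous reference models, assesses every
#' homologue chain against the target (identity, coverage, global and
#' fragment-local r.m.s.d.), rejects those below the identity/coverage
#' thresholds, ranks the survivors by the sum of global and local r.m.s.d.,
#' enumerates candidate protocols, runs each through the backend, and selects
#' the best outcome — by Q-score when geometry percentiles are available from
#' the backend, otherwise by R_free. A protocol file describing the winner is
#' written so later runs can re-execute just that protocol.
#'
#' @param target Path to the target PDB file, or a \code{"pdb_structure"}.
#' @param homologues Character vector of homologue PDB paths, or a named list
#'   of \code{"pdb_structure"} objects.
#' @param options List of settings: \code{min_identity} (75),
#'   \code{min_coverage} (75), \code{max_homologues} (3), \code{cycles} (20),
#'   \code{mr_mode} (FALSE), \code{backend} ([toy_backend]), \code{config}
#'   ([restraint_config()]), \code{protocol_file} (path; when given, only
#'   that protocol is executed), \code{output_dir} (where the winning
#'   protocol file is written; default \code{tempdir()}), \code{results_csv}
#'   (optional path for the per-protocol statistics table), \code{jobs}
#'   (parallel protocol execution; results are aggregated in enumeration
#'   order so the report does not depend on scheduling), \code{seed}.
#' @return An object of class \code{"pipeline_report"}: list with
#'   \code{results} (per-protocol data frame), \code{best} (protocol id),
#'   \code{q_table} (or NULL with \code{fallback = TRUE} when geometry
#'   statistics were unavailable), \code{assessments}, \code{protocols},
#'   \code{best_model}, \code{protocol_file}.
#' @export
run_pipeline <- function(target, homologues = character(), options = list()) {
  opt <- utils::modifyList(
    list(min_identity = 75, min_coverage = 75, max_homologues = 3,
         cycles = 20, mr_mode = FALSE, backend = toy_backend,
         config = restraint_config(), protocol_file = NULL,
         output_dir = tempdir(), results_csv = NULL, jobs = 1, seed = NULL),
    options)
  with_seed(opt$seed, {
    if (is.character(target)) target <- read_structure(target)
    check_structure(target)
    homs <- load_homologues(homologues)

    assessments <- list()
    for (h in homs) {
      a <- tryCatch(assess_homologue(target, h), lrr_error = function(e) NULL)
      if (!is.null(a)) assessments[[length(assessments) + 1]] <- a
    }
    kept <- filter_homologues(assessments, opt$min_identity, opt$min_coverage)
    ranked <- rank_homologues(kept)
    refs <- list()
    for (a in ranked)
      refs[[a$ref_id]] <- as_restraint_ref(a, homs[[a$ref_id]])

    protocols <- enumerate_protocols(ranked, opt$max_homologues, opt$cycles)
    if (!is.null(opt$protocol_file)) {
      p <- load_protocol_file(opt$protocol_file, known_ids = names(refs))
      protocols <- list(p)
    }

    run_one <- function(p) tryCatch(
      run_protocol(p, target, refs, opt$backend, opt$config,
                   options = opt[c("mr_mode", "twin", "scaling")]),
      error = function(e) list(protocol = p$id, r_work = NA_real_,
                               r_free = NA_real_, mp_percentile = NA_real_,
                               model = NULL, failed = conditionMessage(e)))
    outcomes <- if (opt$jobs > 1 && .Platform$OS.type == "unix") {
      parallel::mclapply(protocols, run_one, mc.cores = opt$jobs)
    } else lapply(protocols, run_one)

    results <- do.call(rbind, lapply(outcomes, function(o)
      data.frame(protocol = o$protocol, r_work = o$r_work, r_free = o$r_free,
                 mp_percentile = o$mp_percentile,
                 failed = !is.null(o$failed), stringsAsFactors = FALSE)))
    ok <- !results$failed & !is.na(results$r_free)
    if (!any(ok)) {
      msgs <- vapply(outcomes, function(o) o$failed %||% "no statistics", "")
      stop_lrr("pipeline_error", "all protocols failed:\n",
               paste(sprintf("  %s: %s", results$protocol, msgs), collapse = "\n"))
    }
    usable <- results[ok, , drop = FALSE]
    geometry_available <- !anyNA(usable$mp_percentile)
    q_table <- if (geometry_available) compute_q_scores(usable) else NULL
    best <- select_best_protocol(usable, geometry_available)
    best_outcome <- outcomes[[match(best, results$protocol)]]
    best_protocol <- protocols[[match(best, results$protocol)]]

    if (!dir.exists(opt$output_dir))
      dir.create(opt$output_dir, recursive = TRUE)
    pfile <- file.path(opt$output_dir, "best_protocol.yml")
    save_protocol_file(best_protocol, pfile)
    if (!is.null(opt$results_csv))
      write_protocol_results(results[, c("protocol", "r_work", "r_free",
                                         "mp_percentile")], opt$results_csv)
    structure(list(results = results, best = best, q_table = q_table,
                   fallback = !geometry_available, assessments = assessments,
                   ranked = ranked, protocols = protocols,
                   best_model = best_outcome$model, protocol_file = pfile),
              class = "pipeline_report")
  })
}

load_homologues <- function(homologues) {
  if (is.character(homologues)) {
    homs <- lapply(homologues, read_structure)
  } else {
    homs <- lapply(homologues, function(h) { check_structure(h); h })
  }
  names(homs) <- vapply(homs, `[[`, "", "id")
  if (anyDuplicated(names(homs)))
    stop_lrr("input_error", "duplicate homologue ids: ",
             paste(unique(names(homs)[duplicated(names(homs))]), collapse = ", "))
  homs
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d protocol(s); best: %s%s\n",
              nrow(x$results), x$best,
              if (x$fallback) " (ranked by pseudo-R_free; geometry unavailable)" else ""))
  print(x$results, row.names = FALSE, digits = 4)
  invisible(x)
}

## ---- protocol files ----------------------------------------------------

#' Save / load a protocol file
#'
#' A protocol file is a small YAML document recording the protocol kind, the
#' homologue ids it uses and its stages; supplying one to [run_pipeline()]
#' re-executes only that protocol. The round trip is lossless.
#'
#' @param protocol A \code{"refine_protocol"} (or a \code{"pipeline_report"},
#'   whose best protocol is saved).
#' @param path File path.
#' @return \code{save_protocol_file}: invisibly, \code{path}.
#' @export
save_protocol_file <- function(protocol, path) {
  if (inherits(protocol, "pipeline_report"))
    protocol <- protocol$protocols[[match(protocol$best,
                                          vapply(protocol$protocols, `[[`, "", "id"))]]
  stopifnot(inherits(protocol, "refine_protocol"))
  yaml::write_yaml(list(kind = protocol$kind,
                        homologues = as.list(protocol$homologues),
                        stages = protocol$stages), path)
  invisible(path)
}

#' @rdname save_protocol_file
#' @param known_ids Optional character vector; when given, homologue ids in
#'   the file must all be among them.
#' @return \code{load_protocol_file}: a \code{"refine_protocol"}.
#' @export
load_protocol_file <- function(path, known_ids = NULL) {
  if (!file.exists(path)) stop_lrr("io_error", "file not found: ", path)
  y <- tryCatch(yaml::read_yaml(path),
                error = function(e) stop_lrr("parse_error", "malformed protocol file '",
                                             path, "': ", conditionMessage(e)))
  if (is.null(y$kind) || !y$kind %in% PROTOCOL_KINDS)
    stop_lrr("parse_error", "protocol file '", path, "' has unknown kind '",
             y$kind %||% "<missing>", "'")
  homologues <- as.character(unlist(y$homologues))
  if (!is.null(known_ids)) {
    unknown <- setdiff(homologues, known_ids)
    if (length(unknown))
      stop_lrr("validation_error", "protocol file names unknown homologue(s): ",
               paste(unknown, collapse = ", "))
  }
  p <- new_protocol(y$kind, homologues)
  if (!is.null(y$stages)) {
    stages <- lapply(y$stages, function(s)
      list(restraints = s$restraints, cycles = as.integer(s$cycles %||% 20)))
    want <- if (y$kind == "JELLY") 1L else 2L
    if (length(stages) != want)
      stop_lrr("parse_error", "protocol kind ", y$kind, " must have ", want,
               " stage(s), file has ", length(stages))
    p$stages <- stages
  }
  p
}

#' @export
print.refine_protocol <- function(x, ...) {
  cat(sprintf("<refine_protocol %s> %d stage(s)%s\n", x$id, length(x$stages),
              if (length(x$homologues))
                paste0("; homologues: ", paste(x$homologues, collapse = ", "))
              else ""))
  invisible(x)
}
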