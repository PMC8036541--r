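# End-to-end mutant-panel workflow: run the wild-type docking protocol,
# fit principal axes on the wild-type ensemble, run every mutant with
# the same seed policy, project all ensembles onto the wild-type axes
# and compare them on one shared landscape grid.

#' Wild-type versus mutant dimer landscape comparison
#'
#' Runs the docking protocol on the wild-type system, fits
#' pairwise-distance principal axes on its baseline ensemble, then runs
#' each mutant with the same master seed, projects every ensemble onto
#' the wild-type axes and bins all of them on the wild-type grid.  The
#' summary reports, per construct, the occupancy of the wild-type
#' minimum bin and the minimax barrier from the construct's own minimum
#' to the wild-type minimum.  Any stage failure aborts with the stage
#' name.
#'
#' @param system wild-type \code{dimer_system}.
#' @param mutations named list; each element is a
#'   \code{mutation_edit} or a list of them (applied in order).  An
#'   empty list compares the wild type only.
#' @param ladder a \code{temperature_ladder}.
#' @param schedule a \code{cycle_schedule}.
#' @param n_cycles recorded cycles per construct.
#' @param master_seed shared integer seed (same seed policy for every
#'   construct).
#' @param protocol exchange protocol (default \code{"tiger2"};
#'   \code{"tiger2h"} needs no shell, \code{"tiger2hs"} needs one).
#' @param rigid_body add rigid-body dihedral restraints built per
#'   construct (default TRUE, force constant 25 kcal/(mol deg^2)).
#' @param bins landscape resolution (default 30).
#' @param shell optional \code{shell_spec} for tiger2hs.
#' @param kt thermal energy for Boltzmann inversion; default k_B x
#'   baseline temperature of the ladder.
#' @param out_dir optional directory for per-construct trajectories and
#'   landscape tables.
#' @return object of class \code{mutant_panel}: \code{summary} data
#'   frame, \code{axes}, \code{wt} (ensemble, scores, landscape),
#'   \code{mutants} (named list of the same triple).
#' @export
workflow_mutant_panel <- function(system, mutations = list(), ladder,
                                  schedule, n_cycles, master_seed,
                                  protocol = "tiger2",
                                  rigid_body = TRUE, bins = 30,
                                  shell = NULL, kt = NULL,
                                  out_dir = NULL) {
  stopifnot(inherits(system, "dimer_system"))
  if (is.null(kt)) kt <- kT(ladder$temps[1])
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("mutant panel failed at stage '", name, "': ",
           conditionMessage(e), call. = FALSE))
  }
  run_one <- function(sys) {
    restr <- if (rigid_body) make_rigid_body_restraints(sys) else NULL
    run_protocol(protocol, sys, ladder, schedule, n_cycles, master_seed,
                 restraints = restr, shell = shell)
  }
  idxA <- which(system$chain == "A")
  idxB <- which(system$chain == "B")

  wt_ens <- stage("wild-type sampling", run_one(system))
  axes <- stage("axis fitting", {
    feat <- interchain_distance_features(wt_ens$frames, idxA, idxB,
                                         normalize = TRUE,
                                         box = system$box)
    fit_pca(feat, 2)
  })
  # score through the same raw-feature path used for the mutants, so an
  # identity mutant reproduces the wild type bit for bit
  score_one <- function(ens) {
    raw <- interchain_distance_features(ens$frames, idxA, idxB,
                                        normalize = FALSE,
                                        box = system$box)
    project(raw, axes)
  }
  wt_scores <- stage("wild-type projection", score_one(wt_ens))
  wt_ls <- stage("wild-type landscape",
                 boltzmann_landscape(wt_scores, bins = bins, kt = kt))
  wt_range <- list(x = range(wt_ls$xedges), y = range(wt_ls$yedges))
  wt_min <- landscape_min_bin(wt_ls)

  summarise <- function(name, scores, ls) {
    occ <- score_occupancy(scores, wt_ls, wt_min)
    own_min <- landscape_min_bin(ls)
    barrier <- if (ls$mask[wt_min[1], wt_min[2]]) NA_real_
    else tryCatch(barrier_height(ls, own_min, wt_min),
                  error = function(e) NA_real_)
    data.frame(construct = name, n_frames = nrow(scores),
               wt_min_occupancy = occ,
               barrier_to_wt_min = barrier,
               stringsAsFactors = FALSE)
  }
  summary <- summarise("WT", wt_scores, wt_ls)
  mutants <- list()
  for (nm in names(mutations)) {
    edits <- mutations[[nm]]
    if (inherits(edits, "mutation_edit")) edits <- list(edits)
    sys_m <- stage(paste0("mutation '", nm, "'"), {
      s <- system
      for (e in edits) s <- apply_mutation(s, e)
      s
    })
    ens_m <- stage(paste0("sampling '", nm, "'"), run_one(sys_m))
    sc_m <- stage(paste0("projection '", nm, "'"), score_one(ens_m))
    ls_m <- stage(paste0("landscape '", nm, "'"),
                  boltzmann_landscape(sc_m, bins = bins, kt = kt,
                                      axes_range = wt_range))
    mutants[[nm]] <- list(ensemble = ens_m, scores = sc_m,
                          landscape = ls_m)
    summary <- rbind(summary, summarise(nm, sc_m, ls_m))
  }
  summary$occupancy_vs_wt <- summary$wt_min_occupancy /
    summary$wt_min_occupancy[1]

  out <- structure(list(summary = summary, axes = axes,
                        wt = list(ensemble = wt_ens, scores = wt_scores,
                                  landscape = wt_ls),
                        mutants = mutants, wt_min_bin = wt_min),
                   class = "mutant_panel")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(summary, file.path(out_dir, "panel_summary.csv"),
              row.names = FALSE)
    write_landscape_csv(wt_ls, file.path(out_dir, "landscape_WT.csv"))
    for (nm in names(mutants))
      write_landscape_csv(mutants[[nm]]$landscape,
                          file.path(out_dir,
                                    paste0("landscape_", nm, ".csv")))
  }
  out
}

#' @export
print.mutant_panel <- function(x, ...) {
  cat("mutant_panel:", nrow(x$summary), "constructs\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a landscape as a per-cell CSV table
#'
#' Columns: bin indices, bin-centre coordinates, probability, delta G
#' (empty bins have NA).
#'
#' @param landscape a \code{tiger_landscape}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_landscape_csv <- function(landscape, file) {
  b <- nrow(landscape$prob)
  cx <- (landscape$xedges[-1] + landscape$xedges[-(b + 1)]) / 2
  cy <- (landscape$yedges[-1] + landscape$yedges[-(b + 1)]) / 2
  df <- expand.grid(ix = seq_len(b), iy = seq_len(b))
  df$x <- cx[df$ix]; df$y <- cy[df$iy]
  df$prob <- landscape$prob[cbind(df$ix, df$iy)]
  df$delta_g <- landscape$delta_g[cbind(df$ix, df$iy)]
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Heat-map of a free-energy landscape
#'
#' @param x a \code{tiger_landscape}.
#' @param levels add contour lines at these delta G values (kcal/mol);
#'   NULL for none.
#' @param ... passed to \code{graphics::image}.
#' @return invisibly, \code{x}.
#' @export
plot.tiger_landscape <- function(x, levels = NULL, ...) {
  b <- nrow(x$prob)
  cx <- (x$xedges[-1] + x$xedges[-(b + 1)]) / 2
  cy <- (x$yedges[-1] + x$yedges[-(b + 1)]) / 2
  z <- x$delta_g
  cols <- grDevices::hcl.colors(64, "viridis", rev = TRUE)
  graphics::image(cx, cy, z, col = cols, xlab = "PC1", ylab = "PC2",
                  ...)
  if (!is.null(levels))
    graphics::contour(cx, cy, z, levels = levels, add = TRUE,
                      drawlabels = FALSE)
  invisible(x)
}
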