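# Synthetic plate simulator: renders 4-channel well images (nuclei,
# cytoplasm, LBPA puncta, cholesterol) with known per-cell ground truth.

CHANNEL_ROLES <- c("nuclei", "cytoplasm", "lbpa", "cholesterol")

#' Simulation parameters
#'
#' Geometry, density and intensity parameters of the synthetic screen.
#' Intensities are on a 12-bit scale (arbitrary units, max 4095) stored as
#' 16-bit integers on disk. Cell-to-cell brightness variability is
#' log-normal (multiplicative); camera noise is additive Gaussian on top of
#' a constant background.
#'
#' @param image_size Field size in pixels, `c(height, width)`.
#' @param pixel_size Pixel size in micrometres per pixel.
#' @param fields_per_well Number of imaged fields per well (default 4).
#' @param cells_per_field Mean number of seeded cells per field.
#' @param nucleus_radius Mean and sd of the nucleus semi-axis, micrometres.
#' @param cell_radius Mean and sd of the cell territory radius, micrometres.
#' @param endosomes_per_cell Mean LBPA-positive endosome count per cell.
#' @param endosome_radius Gaussian sigma of a rendered endosome spot,
#'   micrometres.
#' @param nucleus_level,cyto_level Peak intensities of the nuclear and
#'   cytoplasmic stains (a.u.).
#' @param lbpa_spot_level Peak amplitude of one LBPA endosome spot (a.u.).
#' @param chol_diffuse_level Diffuse cytoplasmic filipin intensity (a.u.).
#' @param chol_spot_level Peak amplitude of the endosomal filipin spot (a.u.).
#' @param cell_cv Log-normal sigma of the per-cell brightness factor.
#' @param spot_cv Log-normal sigma of per-spot amplitude variability.
#' @param background Constant background level added to every channel (a.u.).
#' @param noise_sd Additive Gaussian camera noise sd (a.u.).
#' @param perinuclear_width_um Radial width of the perinuclear annulus used
#'   for clustered endosome placement (micrometres; default 4).
#' @param max_intensity Saturation level (default 4095, 12-bit).
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(image_size = c(512L, 512L),
                       pixel_size = 0.5,
                       fields_per_well = 4L,
                       cells_per_field = 100,
                       nucleus_radius = c(mean = 7, sd = 0.8),
                       cell_radius = c(mean = 15, sd = 1.5),
                       endosomes_per_cell = 6,
                       endosome_radius = 0.5,
                       nucleus_level = 1500,
                       cyto_level = 600,
                       lbpa_spot_level = 800,
                       chol_diffuse_level = 150,
                       chol_spot_level = 500,
                       cell_cv = 0.35,
                       spot_cv = 0.4,
                       background = 100,
                       noise_sd = 20,
                       perinuclear_width_um = 4,
                       max_intensity = 4095) {
  abort_if(length(image_size) != 2L || any(image_size < 16),
           "'image_size' must be two pixel lengths >= 16")
  check_scalar_number(pixel_size, "pixel_size", lower = 1e-6)
  abort_if(fields_per_well < 1, "'fields_per_well' must be >= 1")
  check_scalar_number(cells_per_field, "cells_per_field", lower = 0)
  abort_if(length(nucleus_radius) != 2L || any(nucleus_radius <= 0),
           "'nucleus_radius' must be positive c(mean, sd)")
  abort_if(length(cell_radius) != 2L || any(cell_radius <= 0),
           "'cell_radius' must be positive c(mean, sd)")
  check_scalar_number(endosomes_per_cell, "endosomes_per_cell", lower = 0)
  check_scalar_number(endosome_radius, "endosome_radius", lower = 1e-6)
  for (nm in c("nucleus_level", "cyto_level", "lbpa_spot_level",
               "chol_diffuse_level", "chol_spot_level", "background"))
    check_scalar_number(get(nm), nm, lower = 0)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(cell_cv, "cell_cv", lower = 0)
  check_scalar_number(spot_cv, "spot_cv", lower = 0)
  check_scalar_number(perinuclear_width_um, "perinuclear_width_um",
                      lower = 1e-6)
  check_scalar_number(max_intensity, "max_intensity", lower = 1)
  structure(list(
    image_size = as.integer(image_size), pixel_size = pixel_size,
    fields_per_well = as.integer(fields_per_well),
    cells_per_field = cells_per_field,
    nucleus_radius = unname(nucleus_radius), cell_radius = unname(cell_radius),
    endosomes_per_cell = endosomes_per_cell,
    endosome_radius = endosome_radius,
    nucleus_level = nucleus_level, cyto_level = cyto_level,
    lbpa_spot_level = lbpa_spot_level,
    chol_diffuse_level = chol_diffuse_level,
    chol_spot_level = chol_spot_level,
    cell_cv = cell_cv, spot_cv = spot_cv,
    background = background, noise_sd = noise_sd,
    perinuclear_width_um = perinuclear_width_um,
    max_intensity = max_intensity), class = "sim_params")
}

#' Per-compound simulated effect
#'
#' Ground-truth effect of a compound on the simulated phenotype. The
#' baseline (DMSO-like) effect is all-ones with `perinuclear_factor` 0.3
#' and no toxicity.
#'
#' @param lbpa_factor Multiplicative factor on per-endosome LBPA spot
#'   amplitude (>= 0).
#' @param chol_factor Multiplicative factor on the cholesterol (filipin)
#'   signal, both diffuse and endosomal (>= 0).
#' @param endosome_count_factor Multiplicative factor on the mean endosome
#'   count per cell (>= 0).
#' @param perinuclear_factor Fraction in \[0, 1\] of endosomes placed in the
#'   perinuclear annulus (baseline 0.3; clustered phenotype 0.8).
#' @param toxicity_fraction Fraction in \[0, 1\] of seeded cells removed.
#' @return An object of class `compound_effect`.
#' @export
compound_effect <- function(lbpa_factor = 1, chol_factor = 1,
                            endosome_count_factor = 1,
                            perinuclear_factor = 0.3,
                            toxicity_fraction = 0) {
  check_scalar_number(lbpa_factor, "lbpa_factor", lower = 0)
  check_scalar_number(chol_factor, "chol_factor", lower = 0)
  check_scalar_number(endosome_count_factor, "endosome_count_factor",
                      lower = 0)
  check_scalar_number(perinuclear_factor, "perinuclear_factor",
                      lower = 0, upper = 1)
  check_scalar_number(toxicity_fraction, "toxicity_fraction",
                      lower = 0, upper = 1)
  structure(list(lbpa_factor = lbpa_factor, chol_factor = chol_factor,
                 endosome_count_factor = endosome_count_factor,
                 perinuclear_factor = perinuclear_factor,
                 toxicity_fraction = toxicity_fraction),
            class = "compound_effect")
}

#' Fixed control effects
#'
#' The negative control (DMSO) is the baseline effect; the positive
#' control is a U18666A-like dual-lipid phenotype: LBPA and cholesterol
#' both elevated threefold with perinuclear endosome clustering.
#'
#' @return Named list with elements `negative` and `positive`.
#' @export
control_effects <- function() {
  list(negative = compound_effect(),
       positive = compound_effect(lbpa_factor = 3, chol_factor = 3,
                                  perinuclear_factor = 0.8))
}

# painting primitives ---------------------------------------------------------

# Paint a filled ellipse into `mat` (max-combined with existing content).
paint_ellipse <- function(mat, cx, cy, a, b, theta, value) {
  h <- nrow(mat); w <- ncol(mat)
  r <- max(a, b)
  x0 <- max(1L, floor(cx - r)); x1 <- min(w, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(h, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(mat)
  dx <- (x0:x1) - cx; dy <- (y0:y1) - cy
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dy * st, dx * ct, "+") / a   # rotated coordinates / semi-axes
  v <- outer(dy * ct, -dx * st, "+") / b
  inside <- (u * u + v * v) <= 1
  sub <- mat[y0:y1, x0:x1, drop = FALSE]
  sub[inside] <- pmax(sub[inside], value)
  mat[y0:y1, x0:x1] <- sub
  mat
}

# Add Gaussian spots (vectors xs, ys, amps) with common sigma into `mat`.
# Vectorized over spots: one (n_spots x box) evaluation and a single
# index-accumulation pass per call.
paint_spots <- function(mat, xs, ys, amps, sigma) {
  n <- length(xs)
  if (n == 0) return(mat)
  h <- nrow(mat); w <- ncol(mat)
  r <- ceiling(4 * sigma)
  off <- -r:r
  bx <- round(xs); by <- round(ys)
  # box pixel coords and Gaussian values, all spots at once
  px <- outer(bx, off, "+")            # n x (2r+1)
  py <- outer(by, off, "+")
  gx <- exp(-(px - xs)^2 / (2 * sigma^2))
  gy <- exp(-(py - ys)^2 / (2 * sigma^2))
  m <- length(off)
  # expand to the full (2r+1)^2 box per spot
  ix <- px[, rep(seq_len(m), each = m)]         # n x m^2 (x varies slowly)
  iy <- py[, rep(seq_len(m), times = m)]
  val <- (amps * gx)[, rep(seq_len(m), each = m)] *
    gy[, rep(seq_len(m), times = m)]
  keep <- ix >= 1 & ix <= w & iy >= 1 & iy <= h
  idx <- (ix[keep] - 1) * h + iy[keep]
  acc <- rowsum(val[keep], idx)
  pos <- as.integer(rownames(acc))
  mat[pos] <- mat[pos] + acc[, 1]
  mat
}

# Dart-throwing placement of cell centers with a soft minimum distance;
# after `max_tries` failed draws a position is accepted anyway, so touching
# nuclei occur at high density (deliberate: exercises watershed splitting).
place_centers <- function(n, h, w, min_dist, margin, max_tries = 40L) {
  xs <- numeric(n); ys <- numeric(n)
  if (n == 0) return(cbind(x = xs, y = ys))
  for (i in seq_len(n)) {
    for (k in seq_len(max_tries)) {
      x <- runif(1, 1 + margin, w - margin)
      y <- runif(1, 1 + margin, h - margin)
      if (i == 1L) break
      d2 <- (xs[seq_len(i - 1L)] - x)^2 + (ys[seq_len(i - 1L)] - y)^2
      if (min(d2) >= min_dist^2) break
    }
    xs[i] <- x; ys[i] <- y
  }
  cbind(x = xs, y = ys)
}

#' Simulate one well
#'
#' Draws cell positions, shapes, per-cell brightness and endosome spots for
#' every field of one well, renders the four channels (optionally) and
#' returns the exact generator-level ground truth. Deterministic given
#' `seed`: per-field sub-seeds are derived from it, and camera noise uses a
#' separate seed stream so that the ground truth is identical whether or
#' not images are rendered.
#'
#' @param layout_entry One row of a [plate_layout()] (or a list with at
#'   least `well` and `role`).
#' @param effect A [compound_effect()].
#' @param params A [sim_params()].
#' @param seed Integer seed for this well.
#' @param render If `FALSE`, skip image rendering and return ground truth
#'   only.
#' @return A list with elements `images` (a `well_image_set`, or `NULL`
#'   when `render = FALSE`) and `truth` (ground truth: per-cell table,
#'   per-field table, seeded/surviving counts).
#' @export
simulate_well <- function(layout_entry, effect, params, seed, render = TRUE) {
  abort_if(!inherits(effect, "compound_effect"),
           "'effect' must be a compound_effect")
  abort_if(!inherits(params, "sim_params"), "'params' must be sim_params")
  wid <- layout_entry$well
  h <- params$image_size[1]; w <- params$image_size[2]
  px <- params$pixel_size
  rn_mean <- params$nucleus_radius[1] / px
  rn_sd <- params$nucleus_radius[2] / px
  rc_mean <- params$cell_radius[1] / px
  rc_sd <- params$cell_radius[2] / px
  sigma <- params$endosome_radius / px
  ring_px <- params$perinuclear_width_um / px
  tox <- effect$toxicity_fraction

  # seeded cells for the whole well; survivors distributed over fields
  set.seed(derive_seed(seed, 0L, stream = 1L))
  n_seeded <- stats::rpois(1, params$cells_per_field * params$fields_per_well)
  n_surviving <- round(n_seeded * (1 - tox))
  field_of_cell <- if (n_surviving > 0)
    sort(sample.int(params$fields_per_well, n_surviving, replace = TRUE))
  else integer(0)

  fields <- vector("list", params$fields_per_well)
  cell_rows <- vector("list", params$fields_per_well)
  field_rows <- vector("list", params$fields_per_well)
  cell_id0 <- 0L
  for (f in seq_len(params$fields_per_well)) {
    set.seed(derive_seed(seed, f, stream = 2L))
    n <- sum(field_of_cell == f)
    ctr <- place_centers(n, h, w, min_dist = 2.3 * rn_mean,
                         margin = 2)
    a <- pmax(1.5, stats::rnorm(n, rn_mean, rn_sd))
    b <- pmax(1.5, stats::rnorm(n, rn_mean, rn_sd))
    theta <- stats::runif(n, 0, pi)
    rcell <- pmax(pmax(a, b) + 3, stats::rnorm(n, rc_mean, rc_sd))
    fcell <- stats::rlnorm(n, -params$cell_cv^2 / 2, params$cell_cv)
    k <- stats::rpois(n, params$endosomes_per_cell *
                        effect$endosome_count_factor)

    ch <- NULL
    if (render) ch <- lapply(1:4, function(i) matrix(0, h, w))

    # endosome spots for all cells of the field at once
    spot_int_factor <- 2 * pi * sigma^2
    tot <- sum(k)
    cell_of <- rep(seq_len(n), k)
    lbpa_true <- numeric(n); chol_spot_true <- numeric(n)
    k_peri <- integer(n)
    if (tot > 0) {
      rn_s <- pmax(a, b)[cell_of]
      is_peri <- stats::runif(tot) < effect$perinuclear_factor
      # area-uniform radial placement within the perinuclear annulus
      # (clustered fraction) or the whole cytoplasmic annulus
      r_out <- ifelse(is_peri, rn_s + ring_px,
                      pmax(rcell[cell_of] - 1, rn_s + 0.5))
      rad <- sqrt(stats::runif(tot, rn_s^2, r_out^2))
      phi <- stats::runif(tot, 0, 2 * pi)
      sx <- ctr[cell_of, "x"] + rad * cos(phi)
      sy <- ctr[cell_of, "y"] + rad * sin(phi)
      amp_l <- params$lbpa_spot_level * effect$lbpa_factor *
        fcell[cell_of] *
        stats::rlnorm(tot, -params$spot_cv^2 / 2, params$spot_cv)
      amp_c <- params$chol_spot_level * effect$chol_factor *
        fcell[cell_of] *
        stats::rlnorm(tot, -params$spot_cv^2 / 2, params$spot_cv)
      k_peri <- tabulate(cell_of[is_peri], nbins = n)
      lbpa_true <- masked_sums(matrix(cell_of), amp_l, n) * spot_int_factor
      chol_spot_true <- masked_sums(matrix(cell_of), amp_c, n) *
        spot_int_factor
    }
    if (render) {
      # solid stains first (max-combined where cells overlap), then the
      # punctate spots added on top
      for (i in seq_len(n)) {
        ch[[1]] <- paint_ellipse(ch[[1]], ctr[i, "x"], ctr[i, "y"],
                                 a[i], b[i], theta[i],
                                 params$nucleus_level * fcell[i])
        ch[[2]] <- paint_ellipse(ch[[2]], ctr[i, "x"], ctr[i, "y"],
                                 rcell[i], rcell[i], 0,
                                 params$cyto_level * fcell[i])
        ch[[4]] <- paint_ellipse(ch[[4]], ctr[i, "x"], ctr[i, "y"],
                                 rcell[i], rcell[i], 0,
                                 params$chol_diffuse_level *
                                   effect$chol_factor * fcell[i])
      }
      if (tot > 0) {
        ch[[3]] <- paint_spots(ch[[3]], sx, sy, amp_l, sigma)
        ch[[4]] <- paint_spots(ch[[4]], sx, sy, amp_c, sigma)
      }
    }
    nuc_true <- params$nucleus_level * fcell * pi * a * b
    cyto_true <- params$cyto_level * fcell * pi * rcell^2
    chol_true <- params$chol_diffuse_level * effect$chol_factor * fcell *
      pi * rcell^2 + chol_spot_true

    saturated_px <- 0L
    if (render) {
      set.seed(derive_seed(seed, f, stream = 3L))  # noise stream
      img <- array(0, dim = c(h, w, 4))
      for (j in 1:4) {
        v <- ch[[j]] + params$background +
          stats::rnorm(h * w, 0, params$noise_sd)
        saturated_px <- saturated_px + sum(v > params$max_intensity)
        img[, , j] <- pmin(pmax(v, 0), params$max_intensity)
      }
      fields[[f]] <- img
    }
    cell_rows[[f]] <- if (n > 0) data.frame(
      field = f, cell = cell_id0 + seq_len(n),
      x = ctr[, "x"], y = ctr[, "y"],
      nucleus_a = a, nucleus_b = b, nucleus_theta = theta,
      cell_radius = rcell, brightness = fcell,
      endosome_count = k, endosome_count_perinuclear = k_peri,
      nuclei_true = nuc_true, cytoplasm_true = cyto_true,
      lbpa_true = lbpa_true, chol_true = chol_true) else NULL
    cell_id0 <- cell_id0 + n
    field_rows[[f]] <- data.frame(field = f, n_cells = n,
                                  saturated_px = saturated_px)
  }
  truth <- list(
    well_id = wid,
    cells = do.call(rbind, cell_rows[!vapply(cell_rows, is.null, TRUE)]),
    fields = do.call(rbind, field_rows),
    n_seeded = n_seeded, n_surviving = n_surviving)
  if (is.null(truth$cells))
    truth$cells <- data.frame(field = integer(0), cell = integer(0))
  images <- NULL
  if (render)
    images <- well_image_set(fields, pixel_size = px, well_id = wid)
  list(images = images, truth = truth)
}

#' Multi-channel well image set
#'
#' @param fields List of `h x w x 4` arrays (one per imaged field); channel
#'   order is nuclei, cytoplasm, LBPA, cholesterol.
#' @param pixel_size Micrometres per pixel.
#' @param well_id Well identifier.
#' @return An object of class `well_image_set`.
#' @export
well_image_set <- function(fields, pixel_size, well_id) {
  abort_if(length(fields) < 1, "need at least one field")
  dims <- lapply(fields, dim)
  abort_if(any(vapply(dims, length, 1L) != 3L) ||
             any(vapply(dims, `[`, 1L, 3) != 4L),
           "each field must be an h x w x 4 array")
  abort_if(length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L,
           "all fields must have the same shape")
  check_scalar_number(pixel_size, "pixel_size", lower = 1e-9)
  structure(list(fields = fields, channel_roles = CHANNEL_ROLES,
                 pixel_size = pixel_size, well_id = well_id),
            class = "well_image_set")
}

#' Simulate a full plate
#'
#' Simulates every non-empty well of a layout. Control wells use the fixed
#' [control_effects()]; compound wells look up their effect in `effects`.
#' Per-well seeds are derived deterministically from the master seed and
#' the well position, so wells can be simulated in any order with
#' identical results.
#'
#' @param layout A [plate_layout()].
#' @param effects Named list mapping `compound_id` to [compound_effect()].
#' @param params A [sim_params()].
#' @param seed Master integer seed.
#' @param render Render pixel data (`TRUE`) or ground truth only.
#' @return A `plate_dataset`: list with `wells` (per non-empty well: role,
#'   compound_id, images, truth), `layout`, `params`, `seed`.
#' @export
simulate_plate <- function(layout, effects, params, seed, render = TRUE) {
  abort_if(!inherits(layout, "plate_layout"), "'layout' must be a plate_layout")
  ctl <- control_effects()
  todo <- layout[layout$role != "empty", , drop = FALSE]
  need <- todo$role == "compound" & !(todo$compound_id %in% names(effects))
  abort_if(any(need), "missing compound effect for well(s): ",
           paste(todo$well[need], collapse = ", "))
  n_cols <- attr(layout, "n_cols")
  wells <- vector("list", nrow(todo))
  names(wells) <- todo$well
  for (i in seq_len(nrow(todo))) {
    e <- switch(todo$role[i],
                negative_control = ctl$negative,
                positive_control = ctl$positive,
                compound = effects[[todo$compound_id[i]]])
    widx <- (todo$row[i] - 1L) * n_cols + todo$col[i]
    sw <- simulate_well(todo[i, ], e, params,
                        seed = derive_seed(seed, widx), render = render)
    wells[[i]] <- list(well = todo$well[i], role = todo$role[i],
                       compound_id = todo$compound_id[i],
                       images = sw$images, truth = sw$truth)
  }
  structure(list(wells = wells, layout = layout, params = params,
                 seed = seed), class = "plate_dataset")
}

#' Analytic moments of the true per-cell LBPA integrated intensity
#'
#' Closed-form mean and variance of the generator's per-cell LBPA
#' integrated intensity (a compound-Poisson sum of log-normal spot
#' integrals under a log-normal per-cell brightness factor), and the
#' implied well-mean standard deviation. Used as the independent oracle for
#' assay-window (z-prime) calibration.
#'
#' @param params A [sim_params()].
#' @param effect A [compound_effect()].
#' @return List with `mean_cell`, `var_cell`, `n_cells_well`,
#'   `well_mean`, `well_sd` (well-mean sd under the Poisson cell-count
#'   approximation).
#' @export
lbpa_truth_moments <- function(params, effect = compound_effect()) {
  sigma <- params$endosome_radius / params$pixel_size
  mu_spot <- params$lbpa_spot_level * effect$lbpa_factor * 2 * pi * sigma^2
  lambda <- params$endosomes_per_cell * effect$endosome_count_factor
  ef2 <- exp(params$cell_cv^2)     # E[f^2] for mean-1 log-normal f
  eg2 <- exp(params$spot_cv^2)
  mean_cell <- lambda * mu_spot
  var_cell <- lambda * mu_spot^2 * ef2 * eg2 +
    lambda^2 * mu_spot^2 * (ef2 - 1)
  n <- params$cells_per_field * params$fields_per_well *
    (1 - effect$toxicity_fraction)
  list(mean_cell = mean_cell, var_cell = var_cell, n_cells_well = n,
       well_mean = mean_cell, well_sd = sqrt(var_cell / n))
}
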