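# Synthetic trap-movie generator.  Emulates the statistical structure the
# analysis pipeline assumes: a mother cell retained at the centre of a
# microfluidic trap, budding every ~90 min, an abrupt senescence entry point
# (SEP) after which cycles slow down, death, and the trap-level failure
# modes (clogging, mother loss).  Appearance is deliberately schematic —
# disks with brightfield-like rims — not photorealistic yeast.

#' Default parameters of the synthetic cell-history model
#'
#' The defaults describe a desk-scale compressed lifespan: movies of 150
#' frames at 5 min/frame (12.5 h), pre-SEP cycles lognormal with mean 90 min
#' and CV 0.15, an SEP after a mean of ~3.5 generations that doubles the
#' mean cycle duration and adds a linear per-generation slowdown, and a
#' per-generation death probability after the SEP.  Real wild-type lifespans
#' run ~25 generations over days; the compression keeps every downstream
#' property (oscillating labels, SEP break, censoring, clog/empty exclusion)
#' while staying trainable on one CPU.
#'
#' @param T number of frames in the movie.
#' @param frame_interval_min acquisition interval, minutes.
#' @param initial_unbud_range inclusive frame-count range spent unbudded
#'   before the first budding event.
#' @param cycle_mean_min,cycle_cv pre-SEP cycle duration lognormal mean
#'   (minutes) and coefficient of variation.
#' @param sep_enabled simulate a senescence entry point.
#' @param pre_sep_gens_mean pre-SEP generation count is 1 + Poisson(this).
#' @param post_sep_factor,post_sep_slope_min,post_sep_cv post-SEP mean cycle
#'   duration is `post_sep_factor * cycle_mean_min +
#'   post_sep_slope_min * (generation - sep_generation)`, lognormal with CV
#'   `post_sep_cv`.
#' @param death_prob_per_gen constant per-generation death probability
#'   applied after every budding event (geometric lifespan when the SEP is
#'   disabled).
#' @param post_sep_death_prob additional per-generation death probability
#'   after the SEP.
#' @param arrest_prob per-movie probability that the cell permanently stops
#'   dividing without a visible death.
#' @param clog_prob per-movie probability that the trap clogs.
#' @param empty_prob per-movie probability of an empty-trap fate (half of
#'   these are empty from frame 0, half lose the mother mid-movie).
#' @param arrest_hours division-arrest horizon used to classify the true end
#'   reason, hours.
#' @return named list of parameters.
#' @export
synth_params <- function(T = 150L, frame_interval_min = 5,
                         initial_unbud_range = c(2L, 5L),
                         cycle_mean_min = 90, cycle_cv = 0.15,
                         sep_enabled = TRUE, pre_sep_gens_mean = 2.5,
                         post_sep_factor = 2, post_sep_slope_min = 20,
                         post_sep_cv = 0.15,
                         death_prob_per_gen = 0,
                         post_sep_death_prob = 0.35,
                         arrest_prob = 0.03,
                         clog_prob = 0.05, empty_prob = 0.05,
                         arrest_hours = 10) {
  as.list(environment())
}

# Lognormal draw with given mean and CV; CV 0 degenerates to the mean.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one cell's division history
#'
#' Draws budding events, a senescence entry point, and death under the
#' model of [synth_params()], and lays down the per-frame class labels the
#' classifier is expected to recover: `unbud` before the first budding, then
#' within each cycle `small` frames followed by `large` frames (the bud
#' crosses the size threshold mid-cycle), `dead` from the death frame on,
#' with optional `clog`/`empty` trap fates.
#'
#' @param params list from [synth_params()].
#' @param seed integer seed; identical seeds give identical histories.
#' @return a `cell_history` with fields `budding_frames` (0-based),
#'   `sep_frame`/`sep_generation` (`NA` when not reached), `death_frame`,
#'   `end_reason`, `rls`, `per_frame_labels`, `per_frame_sep`
#'   (pre/post state), and `cycle_model_params`.
#' @export
simulate_cell_history <- function(params = synth_params(), seed = 1L) {
  p <- utils::modifyList(synth_params(), params)
  T <- as.integer(p$T)
  if (T < 1L) stop("invalid-parameter: T must be >= 1")
  if (p$frame_interval_min <= 0)
    stop("invalid-parameter: frame_interval_min must be > 0")
  for (nm in c("cycle_mean_min", "cycle_cv", "pre_sep_gens_mean",
               "post_sep_factor", "post_sep_cv"))
    if (p[[nm]] < 0) stop("invalid-parameter: ", nm, " must be >= 0")
  if (p$cycle_mean_min <= 0)
    stop("invalid-parameter: cycle_mean_min must be > 0")

  with_seed(seed, {
    fate <- {
      u <- stats::runif(1)
      if (u < p$clog_prob) "clog"
      else if (u < p$clog_prob + p$empty_prob / 2) "empty_start"
      else if (u < p$clog_prob + p$empty_prob) "empty_leave"
      else if (u < p$clog_prob + p$empty_prob + p$arrest_prob) "arrest"
      else "normal"
    }
    interval <- p$frame_interval_min
    arrest_frames <- ceiling(p$arrest_hours * 60 / interval)

    if (identical(fate, "empty_start")) {
      return(new_cell_history(
        budding = integer(0), cycle_frames = integer(0),
        sep_gen = NA_integer_, death_frame = NA_integer_,
        end_reason = "empty", labels = rep("empty", T), T = T, p = p))
    }

    # Frame at which the trap-level fate interrupts the cell, if any.
    cut_frame <- if (fate %in% c("clog", "empty_leave"))
      sample(seq(floor(T / 4), floor(3 * T / 4)), 1L) else NA_integer_
    arrest_gen <- NA_integer_

    sep_gen <- if (isTRUE(p$sep_enabled))
      2L + stats::rpois(1L, p$pre_sep_gens_mean) else NA_integer_

    u0 <- if (p$initial_unbud_range[1] == p$initial_unbud_range[2])
      p$initial_unbud_range[1]
    else sample(seq(p$initial_unbud_range[1], p$initial_unbud_range[2]), 1L)

    budding <- integer(0)
    cycle_frames <- integer(0)   # rendered (frame-quantised) cycle lengths
    death_frame <- NA_integer_
    f <- as.integer(u0)
    g <- 0L
    while (f < T) {
      g <- g + 1L
      budding <- c(budding, f)
      # duration of generation g
      mean_g <- if (!is.na(sep_gen) && g >= sep_gen)
        p$post_sep_factor * p$cycle_mean_min +
          p$post_sep_slope_min * (g - sep_gen)
      else p$cycle_mean_min
      cv_g <- if (!is.na(sep_gen) && g >= sep_gen) p$post_sep_cv else p$cycle_cv
      dur <- max(2L, as.integer(round(rlnorm_mean_cv(1, mean_g, cv_g) /
                                        interval)))
      cycle_frames <- c(cycle_frames, dur)
      # death check after the budding event
      p_die <- p$death_prob_per_gen +
        if (!is.na(sep_gen) && g >= sep_gen) p$post_sep_death_prob else 0
      if (stats::runif(1) < p_die) {
        death_frame <- f + dur
        break
      }
      if (identical(fate, "arrest") && is.na(arrest_gen) &&
          stats::runif(1) < 0.25) {
        arrest_gen <- g
        break
      }
      f <- f + dur
    }

    labels <- build_labels(T, u0, budding, cycle_frames, death_frame)
    end_reason <- "end_of_movie"

    if (!is.na(death_frame) && death_frame < T) {
      end_reason <- "dead"
    } else death_frame <- NA_integer_

    if (!is.na(cut_frame)) {
      keep <- budding < cut_frame
      budding <- budding[keep]
      cycle_frames <- cycle_frames[keep]
      if (!is.na(death_frame) && death_frame >= cut_frame)
        death_frame <- NA_integer_
      lab <- if (identical(fate, "clog")) "clog" else "empty"
      if (is.na(death_frame) || death_frame >= cut_frame) {
        labels[(cut_frame + 1L):T] <- lab
        end_reason <- if (identical(fate, "clog")) "clog" else "empty"
      }
    } else if (identical(end_reason, "end_of_movie") &&
               length(budding) > 0 &&
               (T - 1L - budding[length(budding)]) > arrest_frames) {
      end_reason <- "arrest"
    }

    if (!is.na(sep_gen) && sep_gen > length(budding)) sep_gen <- NA_integer_
    new_cell_history(budding, cycle_frames, sep_gen, death_frame,
                     end_reason, labels, T, p)
  })
}

# Per-frame labels from the division history (0-based frames; labels[t+1]
# is frame t).  Within each cycle the first ceiling(n/2) frames are 'small'.
build_labels <- function(T, u0, budding, cycle_frames, death_frame) {
  labels <- rep("large", T)
  if (u0 > 0) labels[seq_len(min(u0, T))] <- "unbud"
  for (k in seq_along(budding)) {
    f <- budding[k]
    n <- cycle_frames[k]
    idx <- f + seq_len(min(n, T - f)) - 1L        # 0-based frames of cycle k
    nsmall <- ceiling(n / 2)
    labels[idx + 1L] <- ifelse(seq_along(idx) <= nsmall, "small", "large")
    if (k < length(budding)) {
      gap <- seq.int(f + n, budding[k + 1L] - 1L)  # should be empty
      gap <- gap[gap < T]
      if (length(gap)) labels[gap + 1L] <- "large"
    }
  }
  if (length(budding)) {
    last_end <- budding[length(budding)] + cycle_frames[length(budding)]
    if (last_end < T && (is.na(death_frame) || death_frame > last_end)) {
      labels[(last_end + 1L):T] <- "large"   # arrested / waiting
    }
  }
  if (!is.na(death_frame) && death_frame < T)
    labels[(death_frame + 1L):T] <- "dead"
  labels
}

new_cell_history <- function(budding, cycle_frames, sep_gen, death_frame,
                             end_reason, labels, T, p) {
  sep_frame <- if (!is.na(sep_gen) && sep_gen <= length(budding))
    budding[sep_gen] else NA_integer_
  per_frame_sep <- rep("pre", T)
  if (!is.na(sep_frame)) per_frame_sep[(sep_frame + 1L):T] <- "post"
  structure(list(
    budding_frames = as.integer(budding),
    cycle_durations_min = diff(as.integer(budding)) * p$frame_interval_min,
    cycle_frames = as.integer(cycle_frames),
    sep_frame = sep_frame,
    # 0-based index of the first post-SEP generation
    sep_generation = if (is.na(sep_frame)) NA_integer_
                     else as.integer(sep_gen) - 1L,
    death_frame = death_frame,
    end_reason = end_reason,
    rls = length(budding),
    per_frame_labels = labels,
    per_frame_sep = per_frame_sep,
    T = T,
    frame_interval_min = p$frame_interval_min,
    cycle_model_params = list(pre_mean_min = p$cycle_mean_min,
                              pre_cv = p$cycle_cv,
                              post_mean_min = p$post_sep_factor * p$cycle_mean_min,
                              post_slope_min = p$post_sep_slope_min)
  ), class = "cell_history")
}

#' @export
print.cell_history <- function(x, ...) {
  cat(sprintf("<cell_history> RLS %d, end %s, SEP gen %s, death frame %s\n",
              x$rls, x$end_reason,
              ifelse(is.na(x$sep_generation), "-", x$sep_generation),
              ifelse(is.na(x$death_frame), "-", x$death_frame)))
  invisible(x)
}

#' Default rendering parameters for synthetic trap movies
#'
#' Geometry is expressed as fractions of the image side so the same
#' parameters render at any size >= 32 px.  Intensities are arbitrary units
#' in roughly [0, 1]; noise is additive Gaussian plus a signal-dependent
#' term (`sd = noise_add_sd + noise_mult_sd * sqrt(I)`).
#'
#' @param size (H, W) in pixels.
#' @param mother_radius_frac,bud_max_radius_frac radii as fractions of the
#'   image side.
#' @param background,cell_intensity,rim_intensity,wall_intensity grey levels.
#' @param noise_add_sd,noise_mult_sd noise model parameters (0 disables).
#' @param mother_radius_jitter per-movie fractional SD of the mother
#'   radius (cells differ in size).
#' @param mother_growth_per_gen fractional radius growth per completed
#'   generation (mothers enlarge with replicative age).
#' @param daughter_lifetime frames a separated daughter lingers near the
#'   trap before being washed away.
#' @param fluo_channel render a fluorescence channel with a nuclear blob.
#' @param fluo_baseline total nuclear fluorescence before the SEP (a.u.).
#' @param fluo_rise_rate fractional rise of total nuclear fluorescence per
#'   frame after the SEP.
#' @return named list of parameters.
#' @export
render_params <- function(size = c(60L, 60L), mother_radius_frac = 0.14,
                          mother_radius_jitter = 0.12,
                          mother_growth_per_gen = 0.015,
                          bud_max_radius_frac = 0.13,
                          background = 0.30, cell_intensity = 0.75,
                          rim_intensity = 0.12, wall_intensity = 0.50,
                          noise_add_sd = 0.03, noise_mult_sd = 0.05,
                          daughter_lifetime = 6L, fluo_channel = TRUE,
                          fluo_baseline = 20, fluo_rise_rate = 0.03) {
  as.list(environment())
}

# Rasterise a disk: body and a ~1.2 px rim, painted onto img (H x W).
paint_disk <- function(img, cy, cx, r, body, rim = NULL) {
  H <- nrow(img); W <- ncol(img)
  d2 <- outer((seq_len(H) - 1 - cy)^2, (seq_len(W) - 1 - cx)^2, "+")
  inside <- d2 <= r^2
  img[inside] <- body
  if (!is.null(rim)) {
    ring <- d2 <= r^2 & d2 > (r - 1.2)^2
    img[ring] <- rim
  }
  img
}

disk_mask <- function(H, W, cy, cx, r) {
  outer((seq_len(H) - 1 - cy)^2, (seq_len(W) - 1 - cx)^2, "+") <= r^2
}

# The static trap pattern: two vertical walls flanking the mother position.
trap_pattern <- function(H, W, p) {
  img <- matrix(p$background, H, W)
  wall_w <- max(1L, round(0.05 * W))
  off <- round(0.30 * W)
  cx <- (W - 1) / 2
  rows <- seq_len(round(0.7 * H))
  for (sgn in c(-1, 1)) {
    cols <- round(cx + sgn * off) + seq_len(wall_w) - 1L
    cols <- cols[cols >= 1 & cols <= W]
    img[rows, cols] <- p$wall_intensity
  }
  img
}

#' Render a cell history into a synthetic trap movie with groundtruth
#'
#' Draws, per frame, the trap walls, the central mother disk, a bud disk
#' whose area grows through each cycle and crosses the small/large threshold
#' mid-cycle, recently separated daughters above the trap, a distinct
#' contrast-inverted speckled texture on dead frames, near-full cell cover
#' on clogged frames, and nothing but the trap on empty frames.  A second
#' channel holds a nuclear fluorescence blob whose total intensity rises
#' after the SEP.
#'
#' @param history a `cell_history` from [simulate_cell_history()].
#' @param rparams list from [render_params()].
#' @param seed integer seed (noise, bud angles, distractor placement).
#' @return a `synth_scene`: `movie` (a [trap_movie()]), `truth` (the input
#'   history), `bf_masks` / `nuc_masks` (per-frame [segmentation_mask()]s),
#'   and `nuclear_intensity_trace`.
#' @export
render_trap_movie <- function(history, rparams = render_params(), seed = 1L) {
  p <- utils::modifyList(render_params(), rparams)
  H <- as.integer(p$size[1]); W <- as.integer(p$size[2])
  if (H < 32L || W < 32L)
    stop("invalid-parameter: image must be at least 32x32 px")
  T <- history$T
  side <- min(H, W)
  r_m <- p$mother_radius_frac * side
  r_bud_max <- p$bud_max_radius_frac * side
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  labels <- history$per_frame_labels
  nch <- if (isTRUE(p$fluo_channel)) 2L else 1L

  with_seed(seed, {
    bud_angles <- stats::runif(max(1L, history$rls), -0.6, 0.6) - pi / 2
    r_base <- r_m * min(max(1 + stats::rnorm(1) * p$mother_radius_jitter,
                            0.6), 1.5)
    frames <- array(0, dim = c(T, H, W, nch))
    bf_masks <- vector("list", T)
    nuc_masks <- vector("list", T)
    trace <- numeric(T)
    base <- trap_pattern(H, W, p)

    # frame -> (generation, phase fraction) lookup
    gen_of <- rep(NA_integer_, T); frac_of <- rep(NA_real_, T)
    bf <- history$budding_frames
    for (k in seq_along(bf)) {
      n <- history$cycle_frames[k]
      idx <- bf[k] + seq_len(n) - 1L
      idx <- idx[idx < T]
      gen_of[idx + 1L] <- k
      frac_of[idx + 1L] <- (seq_along(idx) - 1) / n
    }

    # daughters: cycle k's bud separates at bf[k] + n_k and lingers
    daughters <- list()
    if (length(bf) > 1) {
      for (k in seq_len(length(bf) - 1L)) {
        daughters[[k]] <- list(
          start = bf[k] + history$cycle_frames[k],
          end = bf[k] + history$cycle_frames[k] + p$daughter_lifetime,
          angle = bud_angles[k],
          jit = stats::runif(2, -1.5, 1.5))
      }
    }

    for (t0 in seq_len(T) - 1L) {
      lab <- labels[t0 + 1L]
      r_t <- r_base * (1 + p$mother_growth_per_gen * sum(bf <= t0))
      img <- base
      cmap <- matrix(0L, H, W)
      nmap <- matrix(0L, H, W)
      nuc_total <- 0

      if (lab == "clog") {
        # trap overfilled: the mother is still at the centre, buried in
        # other cells that cover >= 50% of the image
        ctrs <- expand.grid(
          cy = seq(r_m, H - r_m, length.out = 4),
          cx = seq(r_m, W - r_m, length.out = 4))
        for (i in seq_len(nrow(ctrs))) {
          dy <- stats::runif(1, -2, 2); dx <- stats::runif(1, -2, 2)
          img <- paint_disk(img, ctrs$cy[i] + dy, ctrs$cx[i] + dx,
                            r_m * 1.05, p$cell_intensity, p$rim_intensity)
          cmap[disk_mask(H, W, ctrs$cy[i] + dy, ctrs$cx[i] + dx,
                         r_m * 1.05)] <- 2L
        }
        img <- paint_disk(img, cy, cx, r_t, p$cell_intensity,
                          p$rim_intensity)
        cmap[disk_mask(H, W, cy, cx, r_t)] <- 1L
      } else if (lab != "empty") {
        # lingering daughters behind the mother
        for (dd in daughters) {
          if (t0 >= dd$start && t0 < dd$end) {
            ddist <- r_t + r_bud_max + 1.5 + 1.2 * (t0 - dd$start)
            dyx <- c(cy + ddist * sin(dd$angle) + dd$jit[1],
                     cx + ddist * cos(dd$angle) + dd$jit[2])
            img <- paint_disk(img, dyx[1], dyx[2], r_bud_max,
                              p$cell_intensity, p$rim_intensity)
            cmap[disk_mask(H, W, dyx[1], dyx[2], r_bud_max)] <- 2L
          }
        }
        if (lab == "dead") {
          # contrast inversion + speckle: a distinct, learnable texture
          img <- paint_disk(img, cy, cx, r_t, 0.08)
          dm <- disk_mask(H, W, cy, cx, r_t)
          spk <- dm & matrix(stats::runif(H * W) < 0.30, H, W)
          img[spk] <- 0.9
          cmap[dm] <- 1L
        } else {
          img <- paint_disk(img, cy, cx, r_t, p$cell_intensity,
                            p$rim_intensity)
          cmap[disk_mask(H, W, cy, cx, r_t)] <- 1L
          g <- gen_of[t0 + 1L]
          if (is.na(g) && lab == "large") {
            # post-cycle wait/arrest: labeled large because the last
            # daughter remains in contact with the mother — render it
            ang <- bud_angles[min(max(sum(bf <= t0), 1L),
                                  length(bud_angles))]
            bdist <- r_t + r_bud_max * 0.8
            byx <- c(cy + bdist * sin(ang), cx + bdist * cos(ang))
            img <- paint_disk(img, byx[1], byx[2], r_bud_max,
                              p$cell_intensity, p$rim_intensity)
            bmask <- disk_mask(H, W, byx[1], byx[2], r_bud_max)
            cmap[bmask & cmap == 0L] <- 2L
          }
          if (!is.na(g) && lab %in% c("small", "large")) {
            # bud area grows affinely in cycle time from a visible minimum
            # (a zero-size bud would be indistinguishable from unbud by
            # construction; the small class is defined by a visible bud)
            rb <- r_bud_max * sqrt(0.15 + 0.85 * frac_of[t0 + 1L])
            ang <- bud_angles[min(g, length(bud_angles))]
            bdist <- r_t + rb * 0.8
            byx <- c(cy + bdist * sin(ang), cx + bdist * cos(ang))
            img <- paint_disk(img, byx[1], byx[2], rb, p$cell_intensity,
                              p$rim_intensity)
            bmask <- disk_mask(H, W, byx[1], byx[2], rb)
            cmap[bmask & cmap == 0L] <- 2L
          }
          # nucleus in the fluorescence channel while alive
          if (nch == 2L) {
            sepf <- history$sep_frame
            nuc_total <- p$fluo_baseline *
              (1 + if (!is.na(sepf) && t0 >= sepf)
                p$fluo_rise_rate * (t0 - sepf) else 0)
            rn <- 0.35 * r_t
            nyx <- c(cy + 0.25 * r_t, cx - 0.2 * r_t)
            nmap[disk_mask(H, W, nyx[1], nyx[2], rn)] <- 1L
          }
        }
      }

      fl <- NULL
      if (nch == 2L) {
        fl <- matrix(0.05, H, W)
        if (any(cmap == 1L)) fl[cmap == 1L] <- 0.10
        if (nuc_total > 0 && any(nmap == 1L))
          fl[nmap == 1L] <- fl[nmap == 1L] + nuc_total / sum(nmap == 1L)
      }

      if (p$noise_add_sd > 0 || p$noise_mult_sd > 0) {
        img <- img + stats::rnorm(H * W) *
          (p$noise_add_sd + p$noise_mult_sd * sqrt(pmax(img, 0)))
        if (!is.null(fl))
          fl <- fl + stats::rnorm(H * W) *
            (p$noise_add_sd / 3 + p$noise_mult_sd / 3 * sqrt(pmax(fl, 0)))
      }
      img[img < 0] <- 0
      frames[t0 + 1L, , , 1L] <- img
      if (nch == 2L) {
        fl[fl < 0] <- 0
        frames[t0 + 1L, , , 2L] <- fl
      }
      trace[t0 + 1L] <- nuc_total
      bf_masks[[t0 + 1L]] <- segmentation_mask(cmap)
      nuc_masks[[t0 + 1L]] <- segmentation_mask(
        nmap, class_set = c("background", "nucleus"))
    }

    movie <- trap_movie(frames, history$frame_interval_min,
                        channel_names = if (nch == 2L)
                          c("brightfield", "gfp") else "brightfield",
                        roi_id = "synth")
    structure(list(movie = movie, truth = history, bf_masks = bf_masks,
                   nuc_masks = nuc_masks,
                   nuclear_intensity_trace = trace),
              class = "synth_scene")
  })
}

#' @export
print.synth_scene <- function(x, ...) {
  cat("<synth_scene> ")
  print(x$movie)
  invisible(x)
}

#' Render a synthetic field of view with a jittered trap grid
#'
#' @param rows,cols grid dimensions (0 allowed: blank field).
#' @param spacing_px centre-to-centre spacing of traps, pixels.
#' @param jitter_px SD of the Gaussian jitter applied to each trap position.
#' @param noise_sd additive Gaussian noise SD.
#' @param template_size side of the square trap template, pixels.
#' @param margin_px border margin around the grid.
#' @param seed integer seed.
#' @return list with `image` (H x W matrix), `centers` (n x 2 matrix of
#'   0-based (row, col) template centres), and `template` (the noiseless
#'   trap tile used, for matched filtering).
#' @export
render_field_of_view <- function(rows = 8L, cols = 8L, spacing_px = 40L,
                                 jitter_px = 0, noise_sd = 0,
                                 template_size = 24L, margin_px = 24L,
                                 seed = 1L) {
  if (rows < 0 || cols < 0) stop("invalid-parameter: negative grid")
  if (spacing_px < template_size)
    stop("invalid-parameter: spacing smaller than template")
  p <- render_params(size = c(template_size, template_size),
                     noise_add_sd = 0, noise_mult_sd = 0)
  templ <- trap_pattern(template_size, template_size, p)
  templ <- paint_disk(templ, (template_size - 1) / 2, (template_size - 1) / 2,
                      p$mother_radius_frac * template_size,
                      p$cell_intensity, p$rim_intensity)
  H <- as.integer(2 * margin_px + max(rows - 1, 0) * spacing_px +
                    template_size)
  W <- as.integer(2 * margin_px + max(cols - 1, 0) * spacing_px +
                    template_size)
  img <- matrix(p$background, H, W)
  centers <- matrix(numeric(0), 0, 2)
  half <- (template_size - 1) / 2
  with_seed(seed, {
    if (rows > 0 && cols > 0) {
      for (r in seq_len(rows)) for (cc in seq_len(cols)) {
        cyx <- c(margin_px + (r - 1) * spacing_px,
                 margin_px + (cc - 1) * spacing_px) + half
        if (jitter_px > 0)
          cyx <- cyx + round(stats::rnorm(2, sd = jitter_px))
        tl <- round(cyx - half)
        img[tl[1] + seq_len(template_size),
            tl[2] + seq_len(template_size)] <- templ
        centers <- rbind(centers, tl + half)
      }
    }
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(H * W, sd = noise_sd), H, W)
    list(image = img, centers = centers, template = templ)
  })
}

#' Corrupt a label sequence with classification-like noise
#'
#' Emulates the two error modes a per-frame classifier makes: uniform
#' class flips, and sporadic isolated `dead` misclassifications of a live
#' cell (never two consecutive injected `dead` frames, and never adjacent
#' to a genuine dead frame).
#'
#' @param labels a [label_sequence()].
#' @param noise_spec list with `flip_rate` (scalar or named per-class vector
#'   of uniform flip probabilities) and `dead_rate` (isolated-'dead'
#'   injection probability per live frame); all rates in \[0, 1\].
#' @param seed integer seed.
#' @return a corrupted [label_sequence()] (probabilities dropped); the
#'   number of uniform flips applied is attached as attribute `n_flips`.
#' @export
corrupt_labels <- function(labels, noise_spec = list(flip_rate = 0,
                                                     dead_rate = 0),
                           seed = 1L) {
  stopifnot(inherits(labels, "label_sequence"))
  cls <- trap_classes()
  flip <- noise_spec$flip_rate %||% 0
  dead_rate <- noise_spec$dead_rate %||% 0
  if (length(flip) == 1L && is.null(names(flip)))
    flip <- stats::setNames(rep(flip, 6L), cls)
  if (any(flip < 0 | flip > 1) || dead_rate < 0 || dead_rate > 1)
    stop("invalid-parameter: rates must lie in [0, 1]")
  lab <- labels$labels
  T <- length(lab)
  if (T == 0L) return(labels)
  with_seed(seed, {
    # uniform flips
    pr <- unname(flip[lab])
    do_flip <- stats::runif(T) < pr
    n_flips <- sum(do_flip)
    if (n_flips > 0) {
      alt <- vapply(lab[do_flip], function(l)
        sample(setdiff(cls, l), 1L), character(1))
      lab[do_flip] <- alt
    }
    # isolated 'dead' injections on live frames
    if (dead_rate > 0) {
      orig <- lab
      cand <- stats::runif(T) < dead_rate & orig != "dead"
      for (t in seq_len(T)) {
        if (!cand[t]) next
        prev_dead <- t > 1L && lab[t - 1L] == "dead"
        next_dead <- t < T && orig[t + 1L] == "dead"
        if (!prev_dead && !next_dead) lab[t] <- "dead"
      }
    }
    out <- label_sequence(lab, frame_interval_min = labels$frame_interval_min)
    attr(out, "n_flips") <- n_flips
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
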