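#' LOCUS task geometry and timing configuration
#'
#' Returns the fixed geometry and timing constants of the LOCUS paradigm:
#' two sequentially presented coloured squares, each inside a 9.8 degree
#' square frame centred on a fixation cross, followed by a colour wheel that
#' cues recall of one item. Frames are drawn from a 3 x 5 grid of possible
#' screen locations; any instructed saccade between successive fixation
#' targets has amplitude of at least 8.5 degrees (adjacent grid centres are
#' 10.1 degrees apart). All spatial units are degrees of visual angle, with
#' the origin at screen centre, x rightward and y upward; times are seconds
#' from trial onset.
#'
#' @param frame_size Side length of the stimulus frame (deg).
#' @param min_item_dist Minimum distance between a stimulus square and its
#'   fixation cross (deg).
#' @param grid_rows,grid_cols Dimensions of the grid of candidate frame
#'   centres.
#' @param grid_spacing Centre-to-centre spacing of the frame grid (deg):
#'   frame size plus the 0.3 deg inter-frame gap.
#' @param min_saccade Minimum amplitude of any instructed saccade (deg).
#' @param item_duration Presentation time of each item (s).
#' @param isi Inter-stimulus interval between the two items (s).
#' @param wheel_delay Delay from item-2 offset to colour-wheel onset (s).
#' @param colour_latency Simulated latency from wheel onset to the colour
#'   response (s); a free generator setting, not a fitted quantity.
#' @param location_latency Simulated latency from wheel onset to the location
#'   response (s). The location response time defines the retention interval
#'   tau used by the generative models.
#' @param saccade_latency Simulated latency from a frame change (or wheel
#'   onset) to execution of the instructed saccade (s).
#' @return A list of class \code{"locus_task"}.
#' @export
locus_task <- function(frame_size = 9.8, min_item_dist = 3.82,
                       grid_rows = 3, grid_cols = 5, grid_spacing = 10.1,
                       min_saccade = 8.5,
                       item_duration = 1, isi = 0.5, wheel_delay = 0.5,
                       colour_latency = 2, location_latency = 3,
                       saccade_latency = 0.2) {
  stopifnot(frame_size > 0, min_item_dist > 0, min_item_dist < frame_size / 2 * sqrt(2),
            colour_latency > 0, location_latency > 0, saccade_latency > 0)
  structure(list(frame_size = frame_size, min_item_dist = min_item_dist,
                 grid_rows = grid_rows, grid_cols = grid_cols,
                 grid_spacing = grid_spacing, min_saccade = min_saccade,
                 item_duration = item_duration, isi = isi,
                 wheel_delay = wheel_delay, colour_latency = colour_latency,
                 location_latency = location_latency,
                 saccade_latency = saccade_latency),
            class = "locus_task")
}

#' Candidate frame centres on the screen grid
#'
#' @param task A \code{\link{locus_task}} configuration.
#' @return Matrix with one row per grid location and columns x, y (deg).
#' @export
frame_grid <- function(task = locus_task()) {
  cx <- (seq_len(task$grid_cols) - (task$grid_cols + 1) / 2) * task$grid_spacing
  cy <- (seq_len(task$grid_rows) - (task$grid_rows + 1) / 2) * task$grid_spacing
  g <- expand.grid(x = cx, y = cy)
  as.matrix(g)
}

.conditions <- c("NO_SACCADE", "SAC_AFTER_1", "SAC_AFTER_2", "TWO_SACCADES")

# deterministic sub-seed streams derived from one root seed
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

#' Place a stimulus square within a frame
#'
#' Samples a point uniformly over the admissible region of a frame: inside
#' the \code{frame_size} square centred on the fixation cross, at least
#' \code{min_item_dist} from the cross. Uses rejection sampling from the
#' uniform square, which leaves the accepted draws exactly uniform on the
#' admissible region. Consumes the current R random-number stream.
#'
#' @param frame_centre Numeric length-2, the frame (= fixation) centre (deg).
#' @param task A \code{\link{locus_task}} configuration.
#' @return Numeric length-2 stimulus coordinates (deg).
#' @export
place_stimulus <- function(frame_centre, task = locus_task()) {
  half <- task$frame_size / 2
  repeat {
    off <- stats::runif(2, -half, half)
    if (sqrt(sum(off^2)) >= task$min_item_dist)
      return(frame_centre + off)
  }
}

#' Generate a synthetic LOCUS session
#'
#' Builds a full session of trial designs: balanced random assignment of the
#' four saccade conditions (exactly \code{n_trials/4} each), frame centres on
#' the screen grid, stimulus placement via \code{\link{place_stimulus}},
#' uniform item colours and per-trial colour-wheel rotation, a random probed
#' item, and the deterministic event timeline implied by the task timings.
#' Each trial's randomness comes from its own sub-seed derived from
#' \code{seed}, so trial k is reproducible in isolation.
#'
#' Condition semantics: \code{NO_SACCADE} keeps one fixation throughout;
#' \code{SAC_AFTER_1} moves the frame (hence fixation) between the items;
#' \code{SAC_AFTER_2} keeps one fixation for both items but places the wheel
#' elsewhere; \code{TWO_SACCADES} does both.
#'
#' @param seed Integer root seed.
#' @param n_trials Number of trials; must be divisible by 4.
#' @param task A \code{\link{locus_task}} configuration.
#' @return A data frame of class \code{c("locus_session","data.frame")} with
#'   one row per trial and the columns documented in
#'   \code{\link{write_session}}.
#' @export
generate_session <- function(seed, n_trials = 160, task = locus_task()) {
  if (n_trials %% 4 != 0)
    stop("invalid design: n_trials must be divisible by 4, got ", n_trials)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  cond <- sample(rep(.conditions, n_trials / 4))
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
  grid <- frame_grid(task)
  ng <- nrow(grid)

  rows <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    set.seed(trial_seeds[k])
    ck <- cond[k]
    i1 <- sample.int(ng, 1)
    fix1 <- grid[i1, ]
    if (ck %in% c("SAC_AFTER_1", "TWO_SACCADES")) {
      i2 <- sample(setdiff(seq_len(ng), i1), 1)
    } else i2 <- i1
    fix2 <- grid[i2, ]
    if (ck %in% c("SAC_AFTER_2", "TWO_SACCADES")) {
      iw <- sample(setdiff(seq_len(ng), i2), 1)
    } else iw <- i2
    wheel <- grid[iw, ]
    item1 <- place_stimulus(fix1, task)
    item2 <- place_stimulus(fix2, task)
    t_on1 <- 0
    t_off1 <- t_on1 + task$item_duration
    t_on2 <- t_off1 + task$isi
    t_off2 <- t_on2 + task$item_duration
    t_wheel <- t_off2 + task$wheel_delay
    rows[[k]] <- data.frame(
      trial_id = k, condition = ck,
      fix1_x = fix1[1], fix1_y = fix1[2],
      fix2_x = fix2[1], fix2_y = fix2[2],
      wheel_x = wheel[1], wheel_y = wheel[2],
      item1_x = item1[1], item1_y = item1[2],
      item2_x = item2[1], item2_y = item2[2],
      item1_col = stats::runif(1, 0, 2 * pi),
      item2_col = stats::runif(1, 0, 2 * pi),
      wheel_rot = stats::runif(1, 0, 2 * pi),
      probed = sample(1:2, 1),
      t_item1_on = t_on1, t_item1_off = t_off1,
      t_item2_on = t_on2, t_item2_off = t_off2,
      t_wheel_on = t_wheel,
      t_col_resp = t_wheel + task$colour_latency,
      t_loc_resp = t_wheel + task$location_latency,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("locus_session", "data.frame")
  attr(out, "task") <- task
  attr(out, "seed") <- seed
  out
}

session_task <- function(session) {
  t <- attr(session, "task")
  if (is.null(t)) locus_task() else t
}

#' Saccade counts and timing variables for one item on one trial
#'
#' Computes the retention variables the generative models condition on, for
#' the given item of a trial: \code{tau}, the time from the item's offset to
#' the location response; \code{t}, the time since the first saccade executed
#' after that item was viewed (0 if none); \code{T}, the time since the
#' second such saccade (0 if none); and \code{n}, the number of saccades
#' between viewing the item and responding. Saccades are modelled as executed
#' \code{saccade_latency} seconds after the frame change (item-1 offset) and
#' after wheel onset, in the conditions that instruct them.
#'
#' Item-wise saccade counts by condition: \code{NO_SACCADE} (0, 0);
#' \code{SAC_AFTER_1} (1, 0); \code{SAC_AFTER_2} (1, 1) - both items are
#' viewed at the same fixation, so the wheel saccade follows both;
#' \code{TWO_SACCADES} (2, 1).
#'
#' @param trial One-row data frame from a \code{\link{generate_session}}
#'   session (or a list with the same fields).
#' @param item 1 or 2.
#' @param task A \code{\link{locus_task}} configuration.
#' @return Named list with elements \code{tau}, \code{t}, \code{T},
#'   \code{n_saccades}.
#' @export
condition_timing <- function(trial, item, task = locus_task()) {
  need <- c("condition", "t_item1_off", "t_item2_off", "t_wheel_on", "t_loc_resp")
  miss <- need[!need %in% names(trial)]
  if (length(miss) || anyNA(unlist(trial[need[-1]])))
    stop("missing event in trial timeline: ",
         paste(if (length(miss)) miss else "NA timestamp", collapse = ", "))
  resp <- trial$t_loc_resp
  off <- if (item == 1) trial$t_item1_off else trial$t_item2_off
  tau <- resp - off
  # execution times of the (up to) two instructed saccades
  s1 <- trial$t_item1_off + task$saccade_latency   # frame-change saccade
  s2 <- trial$t_wheel_on + task$saccade_latency    # wheel saccade
  sac <- switch(trial$condition,
    NO_SACCADE   = numeric(0),
    SAC_AFTER_1  = s1,
    SAC_AFTER_2  = s2,
    TWO_SACCADES = c(s1, s2),
    stop("unknown condition: ", trial$condition))
  sac <- sac[sac > off]          # saccades executed after this item was seen
  n <- length(sac)
  tt <- if (n >= 1) resp - sac[1] else 0
  TT <- if (n >= 2) resp - sac[2] else 0
  list(tau = tau, t = tt, T = TT, n_saccades = n)
}

# vectorised timing for a whole session; item may be a vector (recycled)
session_timing <- function(session, item, task = session_task(session)) {
  n <- nrow(session)
  item <- rep_len(item, n)
  resp <- session$t_loc_resp
  off <- ifelse(item == 1, session$t_item1_off, session$t_item2_off)
  s1 <- session$t_item1_off + task$saccade_latency
  s2 <- session$t_wheel_on + task$saccade_latency
  has1 <- session$condition %in% c("SAC_AFTER_1", "TWO_SACCADES") & s1 > off
  has2 <- session$condition %in% c("SAC_AFTER_2", "TWO_SACCADES") & s2 > off
  # first saccade after the item: s1 where present, else s2
  first <- ifelse(has1, s1, ifelse(has2, s2, NA))
  second <- ifelse(has1 & has2, s2, NA)
  data.frame(tau = resp - off,
             t = ifelse(is.na(first), 0, resp - first),
             T = ifelse(is.na(second), 0, resp - second),
             n = has1 + has2)
}

# fixation at which item k was viewed (screen coords), n x 2 matrix
item_fixation <- function(session, item) {
  item <- rep_len(item, nrow(session))
  cbind(ifelse(item == 1, session$fix1_x, session$fix2_x),
        ifelse(item == 1, session$fix1_y, session$fix2_y))
}

item_location <- function(session, item) {
  item <- rep_len(item, nrow(session))
  cbind(ifelse(item == 1, session$item1_x, session$item2_x),
        ifelse(item == 1, session$item1_y, session$item2_y))
}

#' Simulate responses to a session from a generative model
#'
#' Forward-samples location (and nominal colour) responses for every trial of
#' a session under one of the seven generative models, at the given
#' unconstrained parameters. For the dual (retinotopic) models the response
#' is sampled in polar coordinates about the probed item's fixation, with
#' radial and angular variances given by the model's variance schedule at
#' that trial's timing variables; under interference, a trial responds to the
#' distractor's coordinates (evaluated at the distractor's own timing
#' variables) with probability equal to the interference weight. The
#' allocentric model samples isotropic Gaussian error about the stimulus in
#' screen coordinates. Colour responses are the probed colour plus Gaussian
#' noise wrapped to [0, 2*pi) - colour is not modelled and is carried only so
#' response files are complete.
#'
#' @param session A \code{\link{generate_session}} data frame.
#' @param model A \code{\link{locus_model}} (or model id 1..7).
#' @param kappa Named unconstrained parameter vector for \code{model}.
#' @param seed Integer seed.
#' @param colour_sd Nominal colour-report noise (radians).
#' @return Data frame with columns trial_id, resp_col, resp_x, resp_y.
#' @export
simulate_responses <- function(session, model, kappa, seed,
                               colour_sd = 0.3) {
  model <- as_locus_model(model)
  p <- transform_params(kappa, model)
  task <- session_task(session)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  n <- nrow(session)
  probed <- session$probed
  other <- 3L - probed
  tim_t <- session_timing(session, probed, task)
  tim_d <- session_timing(session, other, task)
  fix <- item_fixation(session, probed)      # response origin
  tgt <- item_location(session, probed)
  dis <- item_location(session, other)

  if (model$id == 1) {
    sig <- variance_schedule(model, p, tim_t$tau, tim_t$t, tim_t$T, tim_t$n)
    sd_xy <- sqrt(sig$sigma_xy)
    resp <- tgt + cbind(stats::rnorm(n, 0, sd_xy), stats::rnorm(n, 0, sd_xy))
  } else {
    st <- variance_schedule(model, p, tim_t$tau, tim_t$t, tim_t$T, tim_t$n)
    sdis <- variance_schedule(model, p, tim_d$tau, tim_d$t, tim_d$T, tim_d$n)
    dt <- tgt - fix
    dd <- dis - fix
    r_t <- sqrt(rowSums(dt^2)); th_t <- atan2(dt[, 2], dt[, 1])
    r_d <- sqrt(rowSums(dd^2)); th_d <- atan2(dd[, 2], dd[, 1])
    w <- if (model$interference) p[["interference"]] else 0
    use_d <- stats::runif(n) < w
    mu_r <- ifelse(use_d, r_d, r_t)
    mu_th <- ifelse(use_d, th_d, th_t)
    s_r <- ifelse(use_d, sdis$sigma_r, st$sigma_r)
    s_th <- ifelse(use_d, sdis$sigma_th, st$sigma_th)
    r <- stats::rnorm(n, mu_r, sqrt(s_r))
    th <- stats::rnorm(n, mu_th, sqrt(s_th))
    resp <- fix + cbind(r * cos(th), r * sin(th))
  }
  col_true <- ifelse(probed == 1, session$item1_col, session$item2_col)
  resp_col <- (col_true + stats::rnorm(n, 0, colour_sd)) %% (2 * pi)
  data.frame(trial_id = session$trial_id, resp_col = resp_col,
             resp_x = resp[, 1], resp_y = resp[, 2])
}
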