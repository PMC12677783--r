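# Synthetic ground-truth generators: planted multilayer networks and
# oscillatory multichannel cohorts with scheduled community switches.

#' Construct a community switching schedule
#'
#' A schedule assigns every node a community label within each epoch; the
#' epochs tile the layer axis `1..L` without gaps or overlap, so the ground
#' truth partition of every layer is unambiguous.
#'
#' @param n_nodes number of nodes (channels).
#' @param epochs list of epochs, each a list with `start`, `end` (layer
#'   indices, inclusive) and `labels` (integer vector of length `n_nodes`,
#'   values >= 1).
#' @return Object of class `community_schedule`.
#' @export
community_schedule <- function(n_nodes, epochs) {
  stops <- integer(0)
  for (e in epochs) {
    if (!all(c("start", "end", "labels") %in% names(e)))
      stop("each epoch needs start, end, labels", call. = FALSE)
    if (length(e$labels) != n_nodes)
      stop("epoch label vector length must equal n_nodes", call. = FALSE)
    if (any(e$labels < 1))
      stop("labels must be integers >= 1", call. = FALSE)
    if (e$start > e$end) stop("epoch start > end", call. = FALSE)
    stops <- c(stops, e$start:e$end)
  }
  L <- max(stops)
  if (!identical(sort(stops), 1:L))
    stop("epochs must tile layers 1..L without overlap", call. = FALSE)
  structure(list(n_nodes = n_nodes, epochs = epochs, n_layers = L),
            class = "community_schedule")
}

#' Expand a schedule into a node-by-layer ground-truth label matrix
#'
#' @param schedule a [community_schedule()].
#' @param n_layers number of layers; must equal the schedule's span.
#' @return N x L integer matrix (marked as aligned).
#' @export
expand_schedule <- function(schedule, n_layers = schedule$n_layers) {
  if (n_layers != schedule$n_layers)
    stop("schedule covers ", schedule$n_layers, " layers, not ", n_layers,
         call. = FALSE)
  lab <- matrix(0L, schedule$n_nodes, n_layers)
  for (e in schedule$epochs)
    lab[, e$start:e$end] <- as.integer(e$labels)
  attr(lab, "aligned") <- TRUE
  lab
}

#' Random schedule with coherent group switches
#'
#' Starts from a balanced random partition into `n_communities`; at each
#' epoch boundary one randomly chosen group of nodes moves together into
#' another community (a planted cohesive event) and one further node moves
#' alone (a planted disjoint event).
#'
#' @param n_nodes,n_layers schedule geometry.
#' @param n_epochs number of epochs (>= 1); `n_epochs - 1` switches.
#' @param n_communities number of communities in the initial partition.
#' @param group_size number of nodes moving together per switch.
#' @param seed integer seed.
#' @return A [community_schedule()].
#' @export
random_schedule <- function(n_nodes, n_layers, n_epochs = 4,
                            n_communities = 3, group_size = max(2, n_nodes %/% 5),
                            seed = 1) {
  if (n_epochs > n_layers) stop("more epochs than layers", call. = FALSE)
  rs <- get_rng(seed)
  labels <- as.integer(1 + (rs$perm(n_nodes) %% n_communities))
  bounds <- unique(round(seq(1, n_layers + 1, length.out = n_epochs + 1)))
  epochs <- list()
  for (e in seq_len(length(bounds) - 1L)) {
    if (e > 1L) {
      ids <- sort(unique(labels))
      from <- ids[1 + rs$int(length(ids))]
      cand <- setdiff(ids, from)
      to <- if (length(cand)) cand[1 + rs$int(length(cand))] else from + 1L
      src <- which(labels == from)
      movers <- src[rs$perm(length(src))][seq_len(min(group_size, length(src) - 1L))]
      labels[movers] <- as.integer(to)
      rest <- setdiff(seq_len(n_nodes), movers)
      solo <- rest[1 + rs$int(length(rest))]
      other <- setdiff(sort(unique(labels)), c(labels[solo], to))
      if (length(other)) labels[solo] <- other[1 + rs$int(length(other))]
    }
    epochs[[e]] <- list(start = bounds[e], end = bounds[e + 1L] - 1L,
                        labels = labels)
  }
  community_schedule(n_nodes, epochs)
}

# Seeded RNG helpers isolated from the global .Random.seed.
get_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    s <- get(".Random.seed", .GlobalEnv)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    s
  })
  with_state <- function(f) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    assign(".Random.seed", env$state, .GlobalEnv)
    on.exit({
      env$state <- get(".Random.seed", .GlobalEnv)
      if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
      else rm(".Random.seed", envir = .GlobalEnv)
    })
    f()
  }
  list(
    unif = function(n) with_state(function() runif(n)),
    norm = function(n, sd = 1) with_state(function() rnorm(n, sd = sd)),
    perm = function(n) with_state(function() sample.int(n)),
    int = function(n) with_state(function() sample.int(n, 1L) - 1L)
  )
}

#' Generate a planted multilayer network with its ground-truth partitions
#'
#' Stochastic block model per layer: node pairs sharing the epoch community
#' receive an edge with probability `p_in` and weight `weight_in`, other
#' pairs with probability `p_out` and weight `weight_out`.
#'
#' @param schedule a [community_schedule()].
#' @param p_in,p_out within/between-community edge probabilities
#'   (`0 <= p_out < p_in <= 1`).
#' @param weight_in,weight_out within/between edge weights
#'   (`weight_out < weight_in`).
#' @param n_layers number of layers (must match the schedule).
#' @param seed integer seed; identical seeds give identical networks.
#' @return List with `net` (a [multilayer_network()]) and `truth` (a
#'   [partition_sequence()] expanded from the schedule).
#' @export
generate_planted_multilayer <- function(schedule, p_in = 0.9, p_out = 0.05,
                                        weight_in = 1, weight_out = 0.3,
                                        n_layers = schedule$n_layers,
                                        seed = 1) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1))
    stop("need 0 <= p_out < p_in <= 1", call. = FALSE)
  if (weight_out >= weight_in)
    stop("need weight_out < weight_in", call. = FALSE)
  truth <- expand_schedule(schedule, n_layers)
  N <- schedule$n_nodes
  rs <- get_rng(seed)
  iu <- which(upper.tri(matrix(0, N, N)))
  layers <- lapply(seq_len(n_layers), function(s) {
    lab <- truth[, s]
    same <- outer(lab, lab, "==")[iu]
    p <- ifelse(same, p_in, p_out)
    w <- ifelse(same, weight_in, weight_out)
    edge <- rs$unif(length(iu)) < p
    W <- matrix(0, N, N)
    W[iu] <- ifelse(edge, w, 0)
    W + t(W)
  })
  net <- multilayer_network(layers, node_labels = paste0("n", seq_len(N)))
  P <- partition_sequence(truth, layer_valid = rep(TRUE, n_layers),
                          params = list(planted = TRUE, seed = seed),
                          node_labels = net$node_labels)
  attr(P$labels, "aligned") <- TRUE
  list(net = net, truth = P)
}

#' Cohort specification for the synthetic generator
#'
#' @param n_subjects_per_group subjects per group (20 default).
#' @param group_effects named list per group of
#'   `list(coupling = , switch_rate = )`: `coupling` in (0, 1] scales the
#'   common community oscillation (1 = fully coupled; the remainder of the
#'   oscillatory amplitude is an independent per-channel component), and
#'   `switch_rate` scales the number of scheduled switches.
#' @param sampling_rate Hz (500 default).
#' @param duration seconds (60 default).
#' @param bands named list of band edges ([eeg_bands()]).
#' @param noise_sd additive white Gaussian noise SD, in units of the
#'   per-band oscillation amplitude (0.5 default).
#' @param phase_jitter_sd per-sample SD of the common-phase random walk
#'   (radians); sets the oscillator linewidth and decorrelates distinct
#'   communities sharing a carrier frequency.
#' @param amp_jitter_sd per-channel amplitude jitter SD.
#' @param seed integer master seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects_per_group = 20,
                        group_effects = list(
                          control = list(coupling = 1, switch_rate = 1),
                          patient = list(coupling = 0.5, switch_rate = 1)),
                        sampling_rate = 500, duration = 60,
                        bands = eeg_bands(), noise_sd = 0.5,
                        phase_jitter_sd = 0.05, amp_jitter_sd = 0.1,
                        seed = 1) {
  if (length(group_effects) < 1L)
    stop("at least one group required", call. = FALSE)
  for (g in group_effects) {
    if (g$coupling <= 0 || g$coupling > 1)
      stop("coupling multiplier must lie in (0, 1]", call. = FALSE)
  }
  n <- duration * sampling_rate
  if (abs(n - round(n)) > 1e-9)
    stop("duration * sampling_rate must be an integer", call. = FALSE)
  edges <- do.call(rbind, bands)
  if (any(edges[, 1] >= edges[, 2]) ||
      any(diff(as.vector(t(edges))) < 0))
    stop("bands must be ordered and non-overlapping", call. = FALSE)
  structure(list(n_subjects_per_group = n_subjects_per_group,
                 group_effects = group_effects,
                 sampling_rate = sampling_rate, duration = duration,
                 bands = bands, noise_sd = noise_sd,
                 phase_jitter_sd = phase_jitter_sd,
                 amp_jitter_sd = amp_jitter_sd, seed = seed),
            class = "cohort_spec")
}

#' Generate one synthetic multichannel recording
#'
#' For each band, channels sharing a community in the active epoch carry a
#' common band-limited oscillation: a sinusoid at the band's geometric-mean
#' frequency whose phase performs a slow random walk, independent across
#' communities. The common component is scaled by the group coupling
#' multiplier `c`; the remaining `(1 - c)` of the amplitude is an
#' independent per-channel oscillation of the same kind, so reducing the
#' coupling degrades phase locking without changing band power much.
#' Independent white Gaussian noise is added across the whole record.
#' Community switches occur exactly at epoch boundaries, which align with
#' 2-s window edges when the schedule is expressed in windows.
#'
#' @param schedule a [community_schedule()] (layers = analysis windows).
#' @param spec a [cohort_spec()].
#' @param subject_id subject identifier.
#' @param group group name (must exist in `spec$group_effects`).
#' @param window_s analysis window length used to map epochs to samples.
#' @param seed integer seed (defaults to `spec$seed`).
#' @return A [recording()].
#' @export
generate_recording <- function(schedule, spec, subject_id = "s1",
                               group = names(spec$group_effects)[1],
                               window_s = 2, seed = spec$seed) {
  if (!group %in% names(spec$group_effects))
    stop("unknown group: ", group, call. = FALSE)
  fs <- spec$sampling_rate
  nyq <- fs / 2
  for (b in spec$bands)
    if (b[1] <= 0 || b[2] >= nyq)
      stop("bands must lie strictly inside (0, Nyquist)", call. = FALSE)
  N <- schedule$n_nodes
  n <- as.integer(round(spec$duration * fs))
  wlen <- as.integer(round(window_s * fs))
  cpl <- spec$group_effects[[group]]$coupling
  rs <- get_rng(seed)
  x <- matrix(0, N, n)
  for (b in seq_along(spec$bands)) {
    lo <- spec$bands[[b]][1]
    width <- spec$bands[[b]][2] - lo
    # community labels map to carriers spread across the band interior so
    # that distinct communities decorrelate within one analysis window;
    # a community keeps its carrier across epochs
    carrier <- function(label)
      2 * pi * (lo + width * (0.2 + 0.6 * ((label - 1) %% 4) / 3)) / fs
    amp <- 1 + rs$norm(N, sd = spec$amp_jitter_sd)
    # independent per-channel oscillations: an uncoupled oscillator has its
    # own carrier (uniform in the band interior), not the community's
    own_omega <- 2 * pi * (lo + width * (0.1 + 0.8 * rs$unif(N))) / fs
    own <- matrix(rs$norm(N * n, sd = spec$phase_jitter_sd), N, n)
    own <- t(apply(own, 1, cumsum)) + 2 * pi * rs$unif(N) +
      own_omega * matrix(0:(n - 1), N, n, byrow = TRUE)
    for (e in schedule$epochs) {
      s0 <- (e$start - 1L) * wlen + 1L
      s1 <- min(e$end * wlen, n)
      if (s0 > n) next
      idx <- s0:s1
      tt <- idx - 1
      comms <- sort(unique(e$labels))
      # common phase random walk per community
      for (cm in comms) {
        members <- which(e$labels == cm)
        omega <- carrier(cm)
        drift <- cumsum(rs$norm(length(idx), sd = spec$phase_jitter_sd)) +
          2 * pi * rs$unif(1)
        common <- cos(omega * tt + drift)
        for (i in members) {
          x[i, idx] <- x[i, idx] + amp[i] *
            (cpl * common + (1 - cpl) * cos(own[i, idx]))
        }
      }
    }
  }
  if (spec$noise_sd > 0)
    x <- x + matrix(rs$norm(N * n, sd = spec$noise_sd), N, n)
  labels <- if (N == 19L) channels_1020() else paste0("ch", seq_len(N))
  recording(x, labels, fs, subject_id = subject_id, group = group)
}

#' Generate a synthetic two-group (or multi-group) cohort
#'
#' Every subject gets independent phase and noise draws from a seed derived
#' deterministically from the cohort seed; the group coupling multiplier
#' plants the between-group effect (a coupling deficit lowers downstream
#' cohesion strength), and `switch_rate` rescales the number of scheduled
#' switches via [random_schedule()].
#'
#' @param spec a [cohort_spec()] with at least 2 subjects per group.
#' @param schedule_template a [community_schedule()] shared by all groups
#'   with `switch_rate` 1.
#' @param window_s analysis window length in seconds.
#' @return List of elements `list(recording =, group =, schedule =)`, one
#'   per subject, with attribute `manifest` (data frame of subject_id,
#'   group, seed).
#' @export
generate_cohort <- function(spec, schedule_template, window_s = 2) {
  if (spec$n_subjects_per_group < 2L)
    stop("need >= 2 subjects per group", call. = FALSE)
  groups <- names(spec$group_effects)
  out <- list()
  manifest <- NULL
  counter <- 0L
  n_epochs <- length(schedule_template$epochs)
  for (g in groups) {
    sw <- spec$group_effects[[g]]$switch_rate %||% 1
    sched <- if (sw == 1) schedule_template else
      random_schedule(schedule_template$n_nodes,
                      schedule_template$n_layers,
                      n_epochs = max(1L, 1L + round((n_epochs - 1L) * sw)),
                      seed = spec$seed + 991L)
    for (k in seq_len(spec$n_subjects_per_group)) {
      counter <- counter + 1L
      sid <- sprintf("%s_%02d", g, k)
      sseed <- (spec$seed * 1000L + counter) %% .Machine$integer.max
      rec <- generate_recording(sched, spec, subject_id = sid, group = g,
                                window_s = window_s, seed = sseed)
      out[[counter]] <- list(recording = rec, group = g, schedule = sched)
      manifest <- rbind(manifest,
                        data.frame(subject_id = sid, group = g,
                                   seed = sseed, stringsAsFactors = FALSE))
    }
  }
  attr(out, "manifest") <- manifest
  out
}
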