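#' Simulation configuration
#'
#' Parameters for the synthetic haplotype generators. Rates are population
#' scaled: `theta` and `rho` are per-bp values of \eqn{2N\mu} and \eqn{2Nr}
#' for a haploid Wright--Fisher population of size `n_pop` (the rescaled
#' desk-size population used by the forward simulator); the sweep strength
#' is \eqn{\gamma = 2 N s}.
#'
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @param n_ingroup Number of haploid ingroup samples (default 10).
#' @param n_outgroups Number of single-haplotype outgroups (0, 1 or 2;
#'   default 2: a near and a far outgroup).
#' @param L Chromosome length in bp.
#' @param theta Population mutation rate per bp (> 0, or 0 for no mutation).
#' @param rho Population recombination rate per bp (>= 0).
#' @param sweep Optional list with elements `position` (bp in `[0, L)`),
#'   `gamma` (\eqn{2Ns} > 0) and `tau` (time since fixation, units of
#'   \eqn{2N} generations, >= 0).
#' @param outgroup_divergence Expected substitutions per site on each
#'   outgroup's private branch (star topology, no outgroup polymorphism).
#' @param n_pop Rescaled haploid population size for the forward simulator
#'   (<= 500 keeps runs desk scale).
#' @param chrom Chromosome name for generated alignments.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, n_ingroup = 10L, n_outgroups = 2L, L = 1e5,
                       theta = 0.004, rho = 0.004, sweep = NULL,
                       outgroup_divergence = 0.05, n_pop = 100L,
                       chrom = "chr") {
  .check_scalar(seed, "seed")
  .check_scalar(n_ingroup, "n_ingroup", positive = TRUE)
  if (!n_outgroups %in% 0:2) .stopf("n_outgroups must be 0, 1 or 2")
  .check_scalar(L, "L", positive = TRUE)
  .check_scalar(theta, "theta", nonneg = TRUE)
  .check_scalar(rho, "rho", nonneg = TRUE)
  .check_scalar(outgroup_divergence, "outgroup_divergence", nonneg = TRUE)
  .check_scalar(n_pop, "n_pop", positive = TRUE)
  if (n_pop > 2000) .stopf("n_pop > 2000 is not desk scale; rescale instead")
  if (!is.null(sweep)) {
    if (!all(c("position", "gamma") %in% names(sweep)))
      .stopf("sweep must have elements 'position' and 'gamma'")
    if (is.null(sweep$tau)) sweep$tau <- 0.05
    .check_scalar(sweep$gamma, "sweep$gamma", positive = TRUE)
    .check_scalar(sweep$tau, "sweep$tau", nonneg = TRUE)
    if (sweep$position < 0 || sweep$position >= L)
      .stopf("sweep position must lie in [0, L)")
  }
  if (n_ingroup > n_pop) .stopf("n_ingroup cannot exceed n_pop")
  structure(list(seed = as.integer(seed), n_ingroup = as.integer(n_ingroup),
                 n_outgroups = as.integer(n_outgroups), L = as.integer(L),
                 theta = theta, rho = rho, sweep = sweep,
                 outgroup_divergence = outgroup_divergence,
                 n_pop = as.integer(n_pop), chrom = chrom),
            class = "sim_config")
}

# ---- fast mechanism: equilibrium frequency-spectrum sampler (no LD) -------

# Draw segregating sites independently: S ~ Poisson(theta * L * a1(n)),
# derived count i with probability proportional to 1/i. Suitable for
# SFS-only statistics; pairs of sites are independent by construction.
.simulate_sfs_panel <- function(cfg) {
  n <- cfg$n_ingroup
  a1 <- sum(1 / seq_len(n - 1))
  S <- stats::rpois(1L, cfg$theta * cfg$L * a1)
  S <- min(S, cfg$L)  # infinite-sites on the integer grid
  pos <- sort(sample.int(cfg$L, S)) - 1L
  freq <- sample.int(n - 1L, S, replace = TRUE,
                     prob = 1 / seq_len(n - 1))
  derived <- matrix(FALSE, n, S)
  for (j in seq_len(S))
    derived[sample.int(n, freq[j]), j] <- TRUE
  list(positions = pos, derived = derived, fixed_positions = integer(0))
}

# ---- forward mechanism: haploid Wright-Fisher with recombination ----------

# Population is a logical matrix (individuals x segregating sites), TRUE =
# derived. Initialized at the neutral equilibrium spectrum (independent
# sites), then burned in for `burn` generations to build linkage
# disequilibrium before any sampling or sweep.
.wf_init <- function(N, L, mu, used) {
  a1 <- sum(1 / seq_len(N - 1))
  S <- stats::rpois(1L, 2 * N * mu * L * a1)
  S <- min(S, sum(!used))
  pos <- sample(which(!used), S)
  used[pos] <- TRUE
  freq <- sample.int(N - 1L, S, replace = TRUE, prob = 1 / seq_len(N - 1))
  pop <- matrix(FALSE, N, S)
  for (j in seq_len(S)) pop[sample.int(N, freq[j]), j] <- TRUE
  list(pop = pop, pos = as.numeric(pos), used = used,
       fixed = numeric(0))
}

# One Wright-Fisher generation: fitness-proportional parent sampling,
# Poisson(r*L) crossovers per offspring, Poisson(mu*L*N) new mutations.
.wf_generation <- function(state, N, L, mu, r, fitness = NULL) {
  pop <- state$pop; pos <- state$pos
  S <- ncol(pop)
  prob <- fitness
  p1 <- sample.int(N, N, replace = TRUE, prob = prob)
  off <- pop[p1, , drop = FALSE]
  nbp <- stats::rpois(N, r * L)
  for (j in which(nbp > 0L)) {
    p2 <- sample.int(N, 1L, prob = prob)
    bps <- sort(stats::runif(nbp[j], 0, L))
    odd <- (findInterval(pos, bps) %% 2L) == 1L
    if (any(odd)) off[j, odd] <- pop[p2, odd]
  }
  nmut <- stats::rpois(1L, mu * L * N)
  if (nmut > 0L) {
    free <- which(!state$used)
    nmut <- min(nmut, length(free))
    newpos <- if (nmut == length(free)) free else sample(free, nmut)
    state$used[newpos] <- TRUE
    newcols <- matrix(FALSE, N, nmut)
    newcols[cbind(sample.int(N, nmut, replace = TRUE), seq_len(nmut))] <- TRUE
    off <- cbind(off, newcols)
    pos <- c(pos, as.numeric(newpos))
  }
  state$pop <- off; state$pos <- pos
  state
}

# Drop lost columns (freeing their positions for future mutations); move
# fixed columns to the substitution record (their positions stay used).
.wf_prune <- function(state, N) {
  cs <- colSums(state$pop)
  lost <- cs == 0L
  fixed <- cs == N
  if (any(fixed)) state$fixed <- c(state$fixed, state$pos[fixed])
  if (any(lost)) state$used[floor(state$pos[lost])] <- FALSE
  keep <- !(lost | fixed)
  state$pop <- state$pop[, keep, drop = FALSE]
  state$pos <- state$pos[keep]
  state
}

.wf_run <- function(state, gens, N, L, mu, r, fitness = NULL,
                    prune_every = 4L) {
  g <- 0L
  while (g < gens) {
    state <- .wf_generation(state, N, L, mu, r, fitness)
    g <- g + 1L
    if (g %% prune_every == 0L || g == gens) state <- .wf_prune(state, N)
  }
  state
}

# Forward simulation, optionally with a conditioned-on-fixation sweep.
# Returns sampled derived-allele matrix for n_ingroup haplotypes plus the
# positions fixed since the burn-in (treated as lineage substitutions).
.simulate_forward <- function(cfg, max_attempts = 500L) {
  N <- cfg$n_pop; L <- cfg$L
  mu <- cfg$theta / (2 * N)
  r <- cfg$rho / (2 * N)
  used <- logical(L)
  state <- .wf_init(N, L, mu, used)
  state <- .wf_run(state, gens = 4L * N, N, L, mu, r)
  state$fixed <- numeric(0)  # burn-in fixations predate the "lineage"
  if (!is.null(cfg$sweep)) {
    s <- cfg$sweep$gamma / (2 * N)
    # internal positions are 1-based; the half offset keeps the selected
    # site distinct from any neutral mutation on the integer grid. If the
    # requested bp already carries a neutral mutation, nudge to the nearest
    # free bp (negligible at these map scales).
    site <- cfg$sweep$position + 1L
    if (state$used[site]) {
      free <- which(!state$used)
      if (!length(free)) .stopf("no free site for the sweep allele")
      site <- free[which.min(abs(free - site))]
    }
    realized_position <- site - 1L
    target <- site + 0.5
    state$used[site] <- TRUE
    saved <- state
    fixed_ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      st <- saved
      st$pop <- cbind(st$pop, FALSE)
      st$pop[sample.int(N, 1L), ncol(st$pop)] <- TRUE
      st$pos <- c(st$pos, target)
      sel_col <- function(stt) which(stt$pos == target)
      repeat {
        j <- sel_col(st)
        if (!length(j)) break  # lost (pruned) or fixed (moved to record)
        w <- 1 + s * st$pop[, j]
        st <- .wf_generation(st, N, L, mu, r, fitness = w)
        st <- .wf_prune(st, N)
      }
      if (any(abs(st$fixed - target) < 0.25)) { fixed_ok <- TRUE; break }
    }
    if (!fixed_ok)
      stop(structure(class = c("fasterx_sweep_not_fixed", "error", "condition"),
                     list(message = sprintf(
                       "sweep allele failed to fix in %d attempts (gamma = %g)",
                       max_attempts, cfg$sweep$gamma), call = NULL)))
    state <- st
    post <- as.integer(round(cfg$sweep$tau * 2 * N))
    if (post > 0L) state <- .wf_run(state, post, N, L, mu, r)
  }
  idx <- sample.int(N, cfg$n_ingroup)
  derived <- state$pop[idx, , drop = FALSE]
  seen <- colSums(derived) > 0L  # drop sites invisible in the sample
  derived <- derived[, seen, drop = FALSE]
  pos <- state$pos[seen]
  o <- order(pos)
  # convert 1-based internal coordinates to the 0-based alignment grid
  out <- list(positions = as.integer(floor(pos[o])) - 1L,
              derived = derived[, o, drop = FALSE],
              fixed_positions = as.integer(floor(sort(state$fixed))) - 1L)
  if (!is.null(cfg$sweep)) out$sweep_position <- realized_position
  out
}

# ---- assembly into a haplotype_alignment ----------------------------------

# Attach nucleotide states and outgroup haplotypes. Outgroups sit on
# independent star branches: each receives Poisson(divergence * L) private
# substitutions at sites disjoint from the ingroup's (infinite sites), and
# carries the ancestral allele at every ingroup site.
.assemble_alignment <- function(cfg, panel) {
  bases <- c("A", "C", "G", "T")
  n <- cfg$n_ingroup
  pos_in <- panel$positions
  pos_fix <- setdiff(panel$fixed_positions, pos_in)
  used <- logical(cfg$L)
  used[c(pos_in, pos_fix) + 1L] <- TRUE
  og_pos <- vector("list", cfg$n_outgroups)
  roles_og <- c("outgroup_near", "outgroup_far")[seq_len(cfg$n_outgroups)]
  for (k in seq_len(cfg$n_outgroups)) {
    nsub <- stats::rpois(1L, cfg$outgroup_divergence * cfg$L)
    free <- which(!used)
    nsub <- min(nsub, length(free))
    p <- sort(sample(free, nsub)) - 1L
    used[p + 1L] <- TRUE
    og_pos[[k]] <- p
  }
  all_pos <- sort(unique(c(pos_in, pos_fix, unlist(og_pos))))
  S <- length(all_pos)
  anc <- sample(bases, S, replace = TRUE)
  alt <- vapply(anc, function(b) sample(setdiff(bases, b), 1L), "")
  M <- matrix(rep(anc, each = n + cfg$n_outgroups),
              nrow = n + cfg$n_outgroups)
  # ingroup polymorphic sites
  j_in <- match(pos_in, all_pos)
  if (length(j_in)) {
    der <- panel$derived
    for (jj in seq_along(j_in)) {
      col <- j_in[jj]
      M[seq_len(n)[der[, jj]], col] <- alt[col]
    }
  }
  # ingroup lineage substitutions: all ingroup derived, outgroups ancestral
  j_fix <- match(pos_fix, all_pos)
  for (col in j_fix) M[seq_len(n), col] <- alt[col]
  # outgroup private substitutions
  for (k in seq_len(cfg$n_outgroups)) {
    jo <- match(og_pos[[k]], all_pos)
    for (col in jo) M[n + k, col] <- alt[col]
  }
  rownames(M) <- c(sprintf("mau%02d", seq_len(n)),
                   c("sim_near", "mel_far")[seq_len(cfg$n_outgroups)])
  haplotype_alignment(chrom = cfg$chrom, L = cfg$L, positions = all_pos,
                      alleles = M,
                      roles = c(rep("ingroup", n), roles_og),
                      ancestral = anc)
}

#' Simulate a neutral haplotype alignment
#'
#' Generates `n_ingroup` haplotypes plus outgroups under neutrality. Two
#' mechanisms are available: a fast equilibrium frequency-spectrum sampler
#' (`"sfs"`, independent sites, no linkage disequilibrium) and a forward
#' haploid Wright--Fisher simulation with recombination (`"forward"`),
#' required whenever LD-dependent statistics are under study.
#'
#' Under either mechanism the expected per-site pairwise diversity is
#' `theta` and the expected number of segregating sites is
#' \eqn{\theta L a_1(n)} with \eqn{a_1(n)=\sum_{i<n} 1/i}.
#'
#' @param cfg A [sim_config()] without a sweep.
#' @param mechanism `"sfs"` (default) or `"forward"`.
#' @return A [haplotype_alignment()].
#' @export
simulate_neutral <- function(cfg, mechanism = c("sfs", "forward")) {
  stopifnot(inherits(cfg, "sim_config"))
  mechanism <- match.arg(mechanism)
  if (!is.null(cfg$sweep)) .stopf("cfg carries a sweep; use simulate_sweep()")
  .with_seed(cfg$seed, {
    panel <- if (mechanism == "sfs") .simulate_sfs_panel(cfg)
             else .simulate_forward(cfg)
    .assemble_alignment(cfg, panel)
  })
}

#' Simulate a completed hard selective sweep
#'
#' Forward haploid Wright--Fisher simulation with recombination in which a
#' new beneficial mutation of strength \eqn{\gamma = 2Ns} is introduced at
#' `cfg$sweep$position` after burn-in and conditioned on fixation
#' (unsuccessful attempts restart from the saved pre-sweep state). After
#' fixation the population evolves neutrally for `tau * 2N` generations
#' before sampling, allowing new mutations to accumulate in the swept
#' region. Diversity at the sweep position is reduced relative to matched
#' neutral runs and recovers with distance.
#'
#' @param cfg A [sim_config()] with a `sweep` element.
#' @param max_attempts Attempt budget for conditioning on fixation; an
#'   allele that fails to fix raises an error of class
#'   `fasterx_sweep_not_fixed` rather than returning silently.
#' @return A [haplotype_alignment()]; the realized sweep is recorded in
#'   attribute `"sweep_truth"`.
#' @export
simulate_sweep <- function(cfg, max_attempts = 500L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$sweep)) .stopf("cfg has no sweep; use simulate_neutral()")
  res <- .with_seed(cfg$seed, {
    panel <- .simulate_forward(cfg, max_attempts = max_attempts)
    list(aln = .assemble_alignment(cfg, panel),
         position = panel$sweep_position)
  })
  aln <- res$aln
  attr(aln, "sweep_truth") <- list(position = res$position,
                                   gamma = cfg$sweep$gamma,
                                   s = cfg$sweep$gamma / (2 * cfg$n_pop),
                                   tau = cfg$sweep$tau,
                                   n_pop = cfg$n_pop)
  aln
}
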