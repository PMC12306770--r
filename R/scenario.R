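#' Default shared terminal-product masses
#'
#' Neutral monoisotopic masses of terminal degradation products emitted in
#' every digest of the default scenario: free amino acids (glycine, alanine,
#' leucine, glutamate, phenylalanine) and the amino-sugar monomers and dimers
#' released from EPS polysaccharides. These are the kind of small, broadly
#' shared metabolites that sequential EPS breakdown converges on.
#'
#' @return A named numeric vector of masses in Da.
#' @export
default_shared_terminal_masses <- function() {
  res <- amino_acid_residues()
  aa <- setNames(res$residue_mass + water_mass, res$residue)
  sug <- sugar_masses()
  c(
    glycine = unname(aa[["G"]]),
    alanine = unname(aa[["A"]]),
    leucine = unname(aa[["L"]]),
    glutamate = unname(aa[["E"]]),
    phenylalanine = unname(aa[["F"]]),
    setNames(sug$mass, sug$label)
  )
}

.draw_rates <- function(n, range, min_gap = 0.04) {
  repeat {
    k <- runif(n, range[1], range[2])
    if (n == 1L) {
      return(k)
    }
    if (min(dist(k)) >= min_gap) {
      return(k)
    }
  }
}

#' Define a synthetic multi-digest degradation scenario
#'
#' Describes the ground truth behind a simulated in-vitro EPS digest
#' experiment: several digests (one per EPS source incubated with its enzyme
#' cocktail), each containing depolymerization chains whose substrates are
#' large (near the instrument's upper m/z limit), whose intermediate oligomers
#' are digest-specific, and whose terminal products are either small
#' metabolites shared across all digests or digest-specific fragments.
#'
#' Per digest the default layout is `n_shared_chains` chains ending in a
#' shared terminal mass, `n_specific_chains` chains ending in a
#' digest-specific low-mass terminal, and `n_highmass_chains` two-stage chains
#' ending in a digest-specific high-mass fragment (emulating partial
#' digestion). Substrate stages are planted as "decreased", interior stages as
#' "bell", terminal stages as "increased".
#'
#' @param digests Character vector of digest ids (default three, matching
#'   three degrader EPS digests). Must be non-empty and unique.
#' @param n_shared_chains,n_specific_chains,n_highmass_chains Chains per
#'   digest in each of the three layouts described above.
#' @param n_stages Stages per shared/specific chain (>= 3; high-mass chains
#'   always have 2 stages).
#' @param shared_terminal_masses Masses emitted in every digest; extended
#'   with random masses in 80-430 Da when `n_shared_chains` exceeds its
#'   length.
#' @param timepoints Sampling grid in hours: sorted, starting at 0 and ending
#'   at 24 (hourly by default; the incubation is sampled across 24 h).
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   intensity noise (default 0.2).
#' @param detection_floor Minimum reportable intensity; intensities below it
#'   are reported as missing. Default `1e-4 * initial_amount`, low enough
#'   that a terminal product rising from a censored baseline to the substrate
#'   scale exceeds a log2 fold change of 10.
#' @param mz_window Acquisition window `c(low, high)` in m/z (default
#'   `c(50, 1700)`); ions outside it are absent from the output.
#' @param mode Ionization mode, `"negative"` (default, adduct \eqn{[M-H]^-})
#'   or `"positive"` (\eqn{[M+H]^+}).
#' @param initial_amount Substrate signal at time zero, arbitrary intensity
#'   units.
#' @param rate_range Range from which cleavage rates are drawn, per hour.
#' @param rt_range Range of simulated retention times, minutes.
#' @param seed Integer seed; the same seed reproduces the scenario and its
#'   generated dataset exactly.
#' @param chains Optional pre-built chains: a named list (one element per
#'   digest) of lists of [build_chain()] objects. Terminal stages whose mass
#'   equals a shared terminal mass are treated as shared across digests.
#' @return An object of class `digest_scenario` with elements `digests`,
#'   `chains`, `species` (tibble of ion ground truth: `ion_id`, `mass`,
#'   `rt_min`, `true_category`, `shared`), `shared_terminal_masses`,
#'   `timepoints`, `noise_cv`, `detection_floor`, `mz_window`, `mode`, `seed`.
#' @export
digest_scenario <- function(digests = c("EPS1", "EPS2", "EPS3"),
                            n_shared_chains = 10,
                            n_specific_chains = 2,
                            n_highmass_chains = 1,
                            n_stages = 4,
                            shared_terminal_masses = default_shared_terminal_masses(),
                            timepoints = 0:24,
                            noise_cv = 0.2,
                            detection_floor = NULL,
                            mz_window = c(50, 1700),
                            mode = c("negative", "positive"),
                            initial_amount = 1e6,
                            rate_range = c(0.4, 1.1),
                            rt_range = c(0.5, 8),
                            seed = 1,
                            chains = NULL) {
  mode <- match.arg(mode)
  digests <- as.character(digests)
  if (length(digests) == 0L) {
    abort("digests must be a non-empty character vector")
  }
  if (anyDuplicated(digests)) {
    abort("digest ids must be unique")
  }
  timepoints <- as.numeric(timepoints)
  if (is.unsorted(timepoints, strictly = TRUE)) {
    abort("timepoints must be strictly increasing")
  }
  if (length(timepoints) < 3L || timepoints[1] != 0 ||
      timepoints[length(timepoints)] != 24) {
    abort("timepoints must start at 0 h and end at 24 h (>= 3 points)")
  }
  if (!is.numeric(noise_cv) || length(noise_cv) != 1L || noise_cv < 0) {
    abort("noise_cv must be a single non-negative number")
  }
  if (length(mz_window) != 2L || mz_window[1] >= mz_window[2]) {
    abort("mz_window must be c(low, high) with low < high")
  }
  detection_floor <- detection_floor %||% (1e-4 * initial_amount)
  if (detection_floor < 0) {
    abort("detection_floor must be non-negative")
  }
  if (n_stages < 3L) {
    abort("n_stages must be at least 3 (substrate, intermediate, terminal)")
  }

  built <- withr::with_seed(seed, {
    if (is.null(chains)) {
      .build_default_chains(
        digests, n_shared_chains, n_specific_chains, n_highmass_chains,
        n_stages, shared_terminal_masses, initial_amount, rate_range, rt_range
      )
    } else {
      .adopt_user_chains(digests, chains, shared_terminal_masses, rt_range)
    }
  })

  structure(
    list(
      digests = digests,
      chains = built$chains,
      species = built$species,
      shared_terminal_masses = built$shared_terminal_masses,
      timepoints = timepoints,
      noise_cv = noise_cv,
      detection_floor = detection_floor,
      mz_window = as.numeric(mz_window),
      mode = mode,
      initial_amount = initial_amount,
      seed = as.integer(seed)
    ),
    class = "digest_scenario"
  )
}

.build_default_chains <- function(digests, n_shared, n_specific, n_high,
                                  n_stages, shared_masses, initial_amount,
                                  rate_range, rt_range) {
  shared_masses <- as.numeric(shared_masses)
  if (n_shared > length(shared_masses)) {
    shared_masses <- c(
      shared_masses,
      runif(n_shared - length(shared_masses), 80, 430)
    )
  }
  shared_masses <- shared_masses[seq_len(n_shared)]
  shared_rt <- runif(n_shared, rt_range[1], rt_range[2])
  shared_ids <- sprintf("ion_shared%03d", seq_len(n_shared))

  species <- list()
  if (n_shared > 0L) {
    species$shared <- tibble(
      ion_id = shared_ids, mass = shared_masses, rt_min = shared_rt,
      true_category = "increased", shared = TRUE
    )
  }
  chains <- list()
  n_inter <- n_stages - 2L
  for (d in digests) {
    dchains <- list()
    ci <- 0L
    add_chain <- function(masses, ids, rates) {
      ch <- build_chain(masses, rates, initial_amount)
      list(chain = ch, ion_ids = ids)
    }
    new_species <- function(mass, category, tag) {
      id <- sprintf("ion_%s_%s", d, tag)
      species[[id]] <<- tibble(
        ion_id = id, mass = mass, rt_min = runif(1, rt_range[1], rt_range[2]),
        true_category = category, shared = FALSE
      )
      id
    }
    for (k in seq_len(n_shared)) {
      ci <- ci + 1L
      m_sub <- runif(1, 1500, 1690)
      m_int <- sort(runif(n_inter, shared_masses[k] + 100, m_sub - 100),
                    decreasing = TRUE)
      sub_id <- new_species(m_sub, "decreased", sprintf("c%03d_sub", ci))
      int_ids <- vapply(seq_len(n_inter), function(s) {
        new_species(m_int[s], "bell", sprintf("c%03d_int%d", ci, s))
      }, character(1))
      rates <- c(.draw_rates(n_stages - 1L, rate_range), 0)
      dchains[[ci]] <- add_chain(
        c(m_sub, m_int, shared_masses[k]),
        c(sub_id, int_ids, shared_ids[k]), rates
      )
    }
    for (k in seq_len(n_specific)) {
      ci <- ci + 1L
      m_term <- runif(1, 80, 390)
      m_sub <- runif(1, 1500, 1690)
      m_int <- sort(runif(n_inter, m_term + 100, m_sub - 100),
                    decreasing = TRUE)
      sub_id <- new_species(m_sub, "decreased", sprintf("c%03d_sub", ci))
      int_ids <- vapply(seq_len(n_inter), function(s) {
        new_species(m_int[s], "bell", sprintf("c%03d_int%d", ci, s))
      }, character(1))
      term_id <- new_species(m_term, "increased", sprintf("c%03d_term", ci))
      rates <- c(.draw_rates(n_stages - 1L, rate_range), 0)
      dchains[[ci]] <- add_chain(
        c(m_sub, m_int, m_term), c(sub_id, int_ids, term_id), rates
      )
    }
    for (k in seq_len(n_high)) {
      ci <- ci + 1L
      m_sub <- runif(1, 1655, 1695)
      m_term <- runif(1, 1420, 1550)
      sub_id <- new_species(m_sub, "decreased", sprintf("c%03d_sub", ci))
      term_id <- new_species(m_term, "increased", sprintf("c%03d_term", ci))
      rates <- c(.draw_rates(1L, rate_range), 0)
      dchains[[ci]] <- add_chain(c(m_sub, m_term), c(sub_id, term_id), rates)
    }
    chains[[d]] <- dchains
  }
  list(
    chains = chains,
    species = bind_rows(species),
    shared_terminal_masses = shared_masses
  )
}

.adopt_user_chains <- function(digests, chains, shared_masses, rt_range) {
  if (!all(digests %in% names(chains))) {
    abort("chains must be a named list with one element per digest")
  }
  shared_masses <- as.numeric(shared_masses)
  species <- list()
  shared_seen <- list()
  out <- list()
  for (d in digests) {
    dchains <- list()
    for (ci in seq_along(chains[[d]])) {
      ch <- chains[[d]][[ci]]
      if (!inherits(ch, "kinetic_chain")) {
        abort("each chain must be a kinetic_chain (see build_chain())")
      }
      n <- length(ch$stage_masses)
      cats <- c("decreased", rep("bell", n - 2L), "increased")
      ids <- character(n)
      for (s in seq_len(n)) {
        m <- ch$stage_masses[s]
        is_shared <- s == n && any(abs(shared_masses - m) < 1e-9)
        if (is_shared) {
          key <- sprintf("%.9f", m)
          if (is.null(shared_seen[[key]])) {
            id <- sprintf("ion_shared%03d", length(shared_seen) + 1L)
            shared_seen[[key]] <- id
            species[[id]] <- tibble(
              ion_id = id, mass = m,
              rt_min = runif(1, rt_range[1], rt_range[2]),
              true_category = cats[s], shared = TRUE
            )
          }
          ids[s] <- shared_seen[[key]]
        } else {
          id <- sprintf("ion_%s_c%03d_s%d", d, ci, s)
          species[[id]] <- tibble(
            ion_id = id, mass = m,
            rt_min = runif(1, rt_range[1], rt_range[2]),
            true_category = cats[s], shared = FALSE
          )
          ids[s] <- id
        }
      }
      dchains[[ci]] <- list(chain = ch, ion_ids = ids)
    }
    out[[d]] <- dchains
  }
  list(
    chains = out,
    species = bind_rows(species),
    shared_terminal_masses = shared_masses
  )
}

#' @export
print.digest_scenario <- function(x, ...) {
  cat(
    "<digest_scenario> ", length(x$digests), " digests (",
    paste(x$digests, collapse = ", "), "), ",
    sum(lengths(x$chains)), " chains, ",
    nrow(x$species), " ion species\n",
    "  timepoints: ", length(x$timepoints), " over [",
    min(x$timepoints), ", ", max(x$timepoints), "] h; noise CV ",
    x$noise_cv, "; m/z window [", x$mz_window[1], ", ", x$mz_window[2],
    "]; mode ", x$mode, "; seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}
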