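#' Select the top-energy compounds from a pose ensemble
#'
#' Keeps the single best-energy pose of each compound, then returns the `n`
#' compounds with the lowest (most favorable) docked energy. Ties are broken
#' by compound id (lexicographic).
#'
#' @param poses list of `sm_pose` objects, each with a docked energy (from the
#'   pose file or [pose_energy()]).
#' @param n number of compounds to keep.
#' @return List of `sm_pose`, one per selected compound, sorted by energy.
#' @export
select_top_poses <- function(poses, n = 2000L) {
  if (length(poses) == 0) stop("no poses supplied")
  en <- vapply(poses, function(p) p$energy, numeric(1))
  if (any(is.na(en)))
    stop("every pose needs an energy; compute pose_energy() for poses lacking one")
  ids <- vapply(poses, function(p) p$compound_id, character(1))
  ord <- order(en, ids)
  poses <- poses[ord]; ids <- ids[ord]
  poses <- poses[!duplicated(ids)]
  if (length(poses) < n)
    message("only ", length(poses), " compounds available (requested ", n, ")")
  poses[seq_len(min(n, length(poses)))]
}

#' Build binary interaction profiles from called events
#'
#' One P x C binary matrix per interaction type (H, E, V): cell (p, c) is 1
#' iff at least one event of that type links compound p to residue c. The
#' three profiles share row (compound) and column (residue) ordering.
#'
#' @param events event data frame ([call_interactions()] output, concatenated
#'   over poses).
#' @param compounds character vector of compound ids (row order).
#' @param site an `sm_site`; its residues give the column order.
#' @return Named list of three `sm_profile` objects (`H`, `E`, `V`), each a
#'   list with `matrix`, `type`, `protein_id`.
#' @export
build_profiles <- function(events, compounds, site) {
  res <- site$residues
  out <- lapply(c(H = "H", E = "E", V = "V"), function(ty) {
    m <- matrix(0L, length(compounds), length(res),
                dimnames = list(compounds, res))
    ev <- events[events$type == ty & events$compound_id %in% compounds &
                 events$res %in% res, , drop = FALSE]
    if (nrow(ev)) m[cbind(match(ev$compound_id, compounds), match(ev$res, res))] <- 1L
    structure(list(matrix = m, type = ty, protein_id = site$protein_id),
              class = "sm_profile")
  })
  out
}

#' One-sided critical Z value for a confidence level
#'
#' @param confidence confidence level in (0, 1).
#' @return The standard-normal quantile, rounded to 3 decimals (0.95 gives
#'   1.645).
#' @export
critical_z <- function(confidence = 0.95) {
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1)
    stop("confidence must be in (0, 1)")
  round(stats::qnorm(confidence), 3)
}

#' Permutation Z-scores of per-residue interaction frequencies
#'
#' For each residue (column) the observed interaction frequency f is the
#' column mean of the binary profile. The null is built by independently
#' permuting each compound's row across the binding-site columns (preserving
#' every compound's interaction count), `n_shuffles` times; the per-column
#' mean and standard deviation of the shuffled frequencies give
#' Z = (f - mu) / sigma. Consensus interactions are columns with
#' Z >= [critical_z()] of `confidence`. Degenerate columns with sigma = 0 are
#' consensus iff f > mu.
#'
#' @param profile an `sm_profile` from [build_profiles()].
#' @param n_shuffles number of shuffled profiles.
#' @param seed random seed (required, recorded in the result).
#' @param confidence confidence level for the consensus call.
#' @return Data frame (class `sm_ztable`) with columns `res`, `type`, `f`,
#'   `mu`, `sigma`, `z`, `consensus`; attributes `n_shuffles`, `seed`,
#'   `threshold`.
#' @export
zscore_profile <- function(profile, n_shuffles = 1000L, seed, confidence = 0.95) {
  stopifnot(inherits(profile, "sm_profile"))
  if (missing(seed)) stop("zscore_profile requires an explicit seed")
  m <- profile$matrix
  P <- nrow(m); C <- ncol(m)
  if (P < 2 || C < 2) stop("profile must have at least 2 compounds and 2 residues")
  f <- colMeans(m)
  thr <- critical_z(confidence)
  if (all(m == 0)) {
    message("all-zero ", profile$type, " profile; no consensus computable")
    out <- data.frame(res = colnames(m), type = profile$type, f = f, mu = 0,
                      sigma = 0, z = NA_real_, consensus = FALSE,
                      stringsAsFactors = FALSE)
    return(ztable(out, n_shuffles, seed, thr))
  }
  k <- rowSums(m)
  S <- as.integer(n_shuffles)
  withr_seed <- set_local_seed(seed)
  on.exit(withr_seed(), add = TRUE)
  # Vectorized row-wise shuffling: rank i.i.d. uniform keys within each of the
  # P*S (row, shuffle) slots; a row's k smallest keys mark its shuffled ones.
  # Done in blocks to bound memory.
  counts_all <- matrix(0L, 0, C)
  block <- max(1L, min(S, as.integer(ceiling(2e6 / (P * C)))))
  done <- 0L
  while (done < S) {
    b <- min(block, S - done)
    nr <- P * b
    U <- matrix(stats::runif(nr * C), nr, C)
    o <- order(rep(seq_len(nr), C), U)       # within-row ascending order
    rk <- integer(nr * C)
    rk[o] <- rep(seq_len(C), nr)             # rank of each key within its row
    sel <- matrix(rk, nr, C) <= rep(k, b)
    cnt <- rowsum(sel + 0L, group = rep(seq_len(b), each = P), reorder = FALSE)
    counts_all <- rbind(counts_all, cnt)
    done <- done + b
  }
  freq <- counts_all / P
  mu <- colMeans(freq)
  sigma <- apply(freq, 2, stats::sd)
  z <- ifelse(sigma > 0, (f - mu) / sigma, NA_real_)
  consensus <- ifelse(sigma > 0, z >= thr, f > mu)
  out <- data.frame(res = colnames(m), type = profile$type, f = f, mu = mu,
                    sigma = sigma, z = z, consensus = consensus,
                    stringsAsFactors = FALSE)
  ztable(out, S, seed, thr)
}

ztable <- function(df, n_shuffles, seed, threshold) {
  rownames(df) <- NULL
  attr(df, "n_shuffles") <- n_shuffles
  attr(df, "seed") <- seed
  attr(df, "threshold") <- threshold
  class(df) <- c("sm_ztable", "data.frame")
  df
}

# Scoped RNG: save and restore the caller's random state around seeded steps.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write an interaction profile as TSV
#'
#' Rows are compounds, columns residue ids.
#'
#' @param profile an `sm_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile$matrix, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
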