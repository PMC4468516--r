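#' Default run configuration
#'
#' Returns the full set of tunable parameters of the site-moiety-map pipeline
#' with their defaults. Any subset can be overridden via `...` or loaded from a
#' plain key=value file with [read_config()]. All values are range-checked.
#'
#' @param ... named overrides of individual parameters.
#' @return A named list of class `sm_config` with elements:
#' \describe{
#'   \item{site_radius}{binding-site inclusion radius around the reference
#'     ligand, in Angstrom (default 10).}
#'   \item{top_n}{number of best-energy compounds used to build profiles
#'     (default 2000).}
#'   \item{n_shuffles}{number of row-shuffled profiles for the permutation
#'     null (default 1000).}
#'   \item{confidence}{one-sided confidence level for consensus interactions
#'     (default 0.95, i.e. Z >= 1.645).}
#'   \item{merge_cutoff}{anchor-center distance below which anchors from
#'     different proteins are aligned, Angstrom (default 2).}
#'   \item{core_threshold}{presence fraction above which an aligned anchor
#'     cluster is labeled core (default 0.90).}
#'   \item{min_specific}{minimum member count for a specific cluster
#'     (default 2).}
#'   \item{linkage_cutoff}{single-linkage distance for grouping consensus
#'     interaction events into anchors, Angstrom (default 3.5).}
#'   \item{min_support}{minimum fraction of profiled compounds whose events
#'     must support an anchor (default 0.05).}
#'   \item{member_fraction}{fraction of a consensus residue's events that must
#'     fall in a cluster for the residue to be listed as an anchor member
#'     (default 0.25).}
#'   \item{match_radius}{ligand-atom distance from an anchor center that counts
#'     as occupying the anchor, Angstrom (default 3).}
#'   \item{vdw_threshold}{per-residue summed steric energy at or below which a
#'     van der Waals event is called, kcal/mol (default -0.3).}
#'   \item{strict_moiety}{if TRUE, anchor matching additionally requires a
#'     preferred functional group (default FALSE).}
#'   \item{specific_match_fraction}{fraction of anchor-bearing panel proteins a
#'     compound must match for a specific anchor to count in screening bins
#'     (default 0.5).}
#'   \item{seed}{random seed recorded in provenance (default NA; set per run).}
#' }
#' @seealso [read_config()], [default_plp_params()]
#' @examples
#' cfg <- sm_config(top_n = 500)
#' cfg$merge_cutoff
#' @export
sm_config <- function(...) {
  cfg <- list(
    site_radius = 10.0,
    top_n = 2000L,
    n_shuffles = 1000L,
    confidence = 0.95,
    merge_cutoff = 2.0,
    core_threshold = 0.90,
    min_specific = 2L,
    linkage_cutoff = 3.5,
    min_support = 0.05,
    member_fraction = 0.25,
    match_radius = 3.0,
    vdw_threshold = -0.3,
    strict_moiety = FALSE,
    specific_match_fraction = 0.5,
    seed = NA_integer_
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config parameter(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  class(cfg) <- "sm_config"
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("config validation: ", msg, call. = FALSE)
  chk(is.numeric(cfg$site_radius) && cfg$site_radius > 0, "site_radius must be > 0")
  chk(is.numeric(cfg$top_n) && cfg$top_n >= 1, "top_n must be >= 1")
  chk(is.numeric(cfg$n_shuffles) && cfg$n_shuffles >= 1, "n_shuffles must be >= 1")
  chk(is.numeric(cfg$confidence) && cfg$confidence > 0 && cfg$confidence < 1,
      "confidence must be in (0, 1)")
  chk(cfg$merge_cutoff > 0, "merge_cutoff must be > 0")
  chk(cfg$core_threshold > 0 && cfg$core_threshold <= 1, "core_threshold must be in (0, 1]")
  chk(cfg$min_specific >= 1, "min_specific must be >= 1")
  chk(cfg$linkage_cutoff > 0, "linkage_cutoff must be > 0")
  chk(cfg$min_support >= 0 && cfg$min_support <= 1, "min_support must be in [0, 1]")
  chk(cfg$member_fraction >= 0 && cfg$member_fraction <= 1, "member_fraction must be in [0, 1]")
  chk(cfg$match_radius > 0, "match_radius must be > 0")
  chk(is.numeric(cfg$vdw_threshold), "vdw_threshold must be numeric")
  chk(cfg$specific_match_fraction > 0 && cfg$specific_match_fraction <= 1,
      "specific_match_fraction must be in (0, 1]")
  invisible(cfg)
}

#' Read a plain key=value configuration file
#'
#' Lines are `key = value`; `#` starts a comment; keys are the names accepted
#' by [sm_config()]. Values are parsed as numeric where possible, `TRUE`/`FALSE`
#' as logical.
#'
#' @param path path to the configuration file.
#' @param base configuration to override; defaults to [sm_config()].
#' @return An `sm_config` list.
#' @export
read_config <- function(path, base = sm_config()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(base)) stop("unknown config parameter: ", key)
    parsed <- if (toupper(val) %in% c("TRUE", "FALSE")) {
      as.logical(val)
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (!is.na(num)) num else val
    }
    base[[key]] <- parsed
  }
  validate_config(base)
  class(base) <- "sm_config"
  base
}

# short deterministic fingerprint of a config, for provenance blocks
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x) paste(format(x), collapse = ","),
                                character(1)), sep = "=", collapse = ";")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}

provenance_block <- function(cfg, seed = cfg$seed, extra = list()) {
  c(list(tool = "sitemoiety",
         version = as.character(utils::packageVersion("sitemoiety")),
         config_hash = config_hash(cfg),
         seed = if (is.na(seed)) NULL else as.integer(seed),
         config = unclass(cfg)),
    extra)
}
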