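# internal: read a packaged survey summary table
read_survey_table <- function(name) {
  path <- system.file("extdata", name, package = "resmon")
  if (path == "") stop("packaged table not found: ", name)
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Packaged reference-survey summary tables
#'
#' Loads the transcribed summary tables of the reference monitoring survey
#' (1,146 fruit and vegetable samples, 20 commodities, 400 pesticides
#' screened): the occurrence-by-commodity table, the incidence-by-pesticide
#' table, the per-pair dietary exposure table (printed ESTI/aHQ/EDI/HQ
#' cells), and the method-validation table for the 15 validated pesticides.
#' Together these form the specification from which
#' [build_survey_fixture()] deterministically reconstructs a sample-level
#' dataset.
#'
#' @return An object of class `"fixture_spec"`: a list with data frames
#'   `occurrence`, `incidence`, `exposure`, `validation`, the
#'   pesticide x commodity `pairs` implied by the exposure table, and the
#'   `pls_default_mrl` in force (0.01 mg/kg).
#' @export
survey_fixture_spec <- function() {
  exposure <- read_survey_table("survey_exposure.csv")
  structure(
    list(occurrence = read_survey_table("survey_occurrence.csv"),
         incidence = read_survey_table("survey_incidence.csv"),
         exposure = exposure,
         validation = read_survey_table("survey_validation.csv"),
         pairs = exposure[, c("pesticide", "commodity")],
         pls_default_mrl = 0.01),
    class = "fixture_spec")
}

# internal: integral transportation solve (supplies -> demands over the
# allowed support) via max-flow; returns the pair table with an `n` column,
# or NULL when the marginals are infeasible
solve_transport <- function(supply, demand, pairs) {
  total <- sum(supply)
  out <- pairs
  out$n <- 0L
  if (abs(total - sum(demand)) > 1e-9) return(NULL)
  if (total == 0) return(out)
  sv <- paste0("p\r", names(supply))
  dv <- paste0("c\r", names(demand))
  edges <- rbind(
    data.frame(from = "..s..", to = sv, cap = as.numeric(supply),
               stringsAsFactors = FALSE),
    data.frame(from = paste0("p\r", pairs$pesticide),
               to = paste0("c\r", pairs$commodity),
               cap = total, stringsAsFactors = FALSE),
    data.frame(from = dv, to = "..t..", cap = as.numeric(demand),
               stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges)
  mf <- igraph::max_flow(g, source = "..s..", target = "..t..",
                         capacity = edges$cap)
  if (mf$value < total - 1e-9) return(NULL)
  flow <- mf$flow[seq(length(supply) + 1, length.out = nrow(pairs))]
  if (any(abs(flow - round(flow)) > 1e-6))
    stop("internal error: non-integral transportation flow")
  out$n <- as.integer(round(flow))
  out
}

# internal: choose per-pair MRLs and detected concentrations for one
# pesticide so that verdicts and the detected range reproduce the spec
place_concentrations <- function(pesticide, inc_row, pr) {
  lo <- inc_row$conc_min; hi <- inc_row$conc_max
  m_lo <- inc_row$mrl_min; m_hi <- inc_row$mrl_max
  if (!(lo > 0 && lo <= hi && m_lo > 0 && m_lo <= m_hi))
    stop("infeasible incidence row for ", pesticide)
  pr <- pr[order(pr$commodity), , drop = FALSE]
  above_idx <- which(pr$n_above > 0)
  below_idx <- which(pr$n_below > 0)

  mrl <- rep(m_hi, nrow(pr))
  if (length(above_idx) > 0) {
    mrl[above_idx[1]] <- m_lo
  } else if (nrow(pr) == 1) {
    mrl[1] <- if (hi <= m_lo) m_lo else m_hi
  } else if (lo <= m_lo) {
    mrl[below_idx[1]] <- m_lo
  }

  for (i in above_idx)
    if (!(mrl[i] < hi))
      stop("cannot place a violation for ", pesticide, " in ",
           pr$commodity[i], ": MRL ", mrl[i], " >= max concentration ", hi)

  minh <- if (length(below_idx) > 0) below_idx[1] else above_idx[1]
  maxh <- if (length(above_idx) > 0) {
    above_idx[length(above_idx)]
  } else {
    cand <- which(pr$n_below > 0 & mrl >= hi)
    if (length(cand) == 0)
      stop("no pair of ", pesticide, " can hold the maximum concentration ",
           hi, " below its MRL")
    cand[length(cand)]
  }
  if (minh == maxh && lo != hi && pr$n_below[minh] + pr$n_above[minh] < 2)
    stop("single slot of ", pesticide,
         " cannot hold both range endpoints")

  geom_seq <- function(a, b, k) {
    if (k == 0) return(numeric(0))
    if (a == b) return(rep(a, k))
    exp(seq(log(a), log(b), length.out = k))
  }
  rows <- list()
  for (i in seq_len(nrow(pr))) {
    kb <- pr$n_below[i]
    if (kb > 0) {
      ub <- min(mrl[i], hi)
      if (lo > ub)
        stop("no compliant concentration in [", lo, ", ", ub, "] for ",
             pesticide, " in ", pr$commodity[i])
      vals <- geom_seq(lo, ub, kb + 2)[seq(2, kb + 1)]
      if (i == minh) vals[1] <- lo
      if (i == maxh && pr$n_above[i] == 0) vals[kb] <- hi
      rows[[length(rows) + 1]] <- data.frame(
        commodity = pr$commodity[i], concentration = vals,
        mrl = mrl[i], stringsAsFactors = FALSE)
    }
    ka <- pr$n_above[i]
    if (ka > 0) {
      gm <- sqrt(mrl[i] * hi)
      vals <- geom_seq(gm, hi, ka + 1)[seq_len(ka)]
      if (i == maxh) vals[ka] <- hi
      if (i == minh && kb == 0) {
        if (lo <= mrl[i])
          stop("minimum concentration ", lo, " of ", pesticide,
               " cannot violate MRL ", mrl[i])
        vals[1] <- lo
      }
      rows[[length(rows) + 1]] <- data.frame(
        commodity = pr$commodity[i], concentration = vals,
        mrl = mrl[i], stringsAsFactors = FALSE)
    }
  }
  conc <- do.call(rbind, rows)
  conc$pesticide <- pesticide
  mrls <- data.frame(pesticide = pesticide, commodity = pr$commodity,
                     mrl = mrl, stringsAsFactors = FALSE)
  list(concentrations = conc, mrls = mrls)
}

#' Deterministically reconstruct a sample-level dataset from summary tables
#'
#' Builds a complete monitoring dataset (samples, measurements, MRL and
#' toxicological reference tables) whose classification reproduces the
#' supplied occurrence and incidence marginals exactly. The
#' pesticide-to-commodity allocation is solved as an integral
#' transportation problem (max-flow over the allowed pairs, violations
#' first, then one detection per remaining pair, then the residual
#' detections); concentrations are placed geometrically inside the
#' feasible interval of each pair so that every verdict and each
#' pesticide's detected range come out as specified. The construction
#' is a deterministic function of the spec: no randomness is involved.
#'
#' Reconstructed samples carry one residue each, which is forced by the
#' reference survey's accounting (91 contaminated samples, 91
#' detections); the stochastic generator
#' ([generate_monitoring_dataset()]) covers the multi-residue case
#' instead.
#'
#' @param spec A fixture specification as returned by
#'   [survey_fixture_spec()], or any list with compatible `occurrence`,
#'   `incidence` and `pairs` entries (and optionally `exposure`,
#'   `validation`, `pls_default_mrl`).
#' @return An object of class `"survey_fixture"`: a list with `samples`,
#'   `measurements`, `mrl_table`, `tox_table` (NULL without an exposure
#'   table) and `exposure` (the spec's exposure table, carried through
#'   for replay analyses).
#' @export
build_survey_fixture <- function(spec = survey_fixture_spec()) {
  occ <- spec$occurrence
  inc <- spec$incidence
  pairs <- unique(spec$pairs)
  pls <- if (is.null(spec$pls_default_mrl)) 0.01 else spec$pls_default_mrl

  if (!all(occ$n_without + occ$n_below + occ$n_above == occ$n_total))
    stop("occurrence row(s) do not sum to n_total: ",
         paste(occ$product[occ$n_without + occ$n_below + occ$n_above !=
                             occ$n_total], collapse = ", "))
  if (any(inc$n_above > inc$n_detected))
    stop("incidence row(s) with n_above > n_detected: ",
         paste(inc$pesticide[inc$n_above > inc$n_detected], collapse = ", "))
  if (sum(occ$n_below + occ$n_above) != sum(inc$n_detected))
    stop("inconsistent marginals: commodities carry ",
         sum(occ$n_below + occ$n_above), " detections but pesticides sum to ",
         sum(inc$n_detected))
  if (!all(pairs$pesticide %in% inc$pesticide) ||
      !all(pairs$commodity %in% occ$product))
    stop("allowed pairs reference unknown pesticides/commodities")

  sup_a <- setNames(inc$n_above, inc$pesticide)
  dem_a <- setNames(occ$n_above, occ$product)
  A <- solve_transport(sup_a, dem_a, pairs)
  if (is.null(A))
    stop("infeasible marginals: MRL violations cannot be allocated ",
         "to the allowed pairs")

  lb <- as.integer(A$n == 0)  # every allowed pair carries >= 1 detection
  row_lb <- tapply(lb, pairs$pesticide, sum)
  col_lb <- tapply(lb, pairs$commodity, sum)
  sup_b <- setNames(inc$n_detected - inc$n_above, inc$pesticide)
  sup_b <- sup_b - ifelse(is.na(row_lb[names(sup_b)]), 0,
                          row_lb[names(sup_b)])
  dem_b <- setNames(occ$n_below, occ$product)
  dem_b <- dem_b - ifelse(is.na(col_lb[names(dem_b)]), 0,
                          col_lb[names(dem_b)])
  if (any(sup_b < 0))
    stop("infeasible marginals: pesticide(s) have fewer detections than ",
         "allowed pairs: ", paste(names(sup_b)[sup_b < 0], collapse = ", "))
  if (any(dem_b < 0))
    stop("infeasible marginals: commodity(ies) have fewer below-MRL ",
         "samples than allowed pairs require: ",
         paste(names(dem_b)[dem_b < 0], collapse = ", "))
  B <- solve_transport(sup_b, dem_b, pairs)
  if (is.null(B))
    stop("infeasible marginals: below-MRL detections cannot be allocated ",
         "to the allowed pairs")
  pairs$n_above <- A$n
  pairs$n_below <- B$n + lb

  placed <- lapply(inc$pesticide, function(p) {
    place_concentrations(p, inc[inc$pesticide == p, ],
                         pairs[pairs$pesticide == p, , drop = FALSE])
  })
  conc <- do.call(rbind, lapply(placed, `[[`, "concentrations"))
  mrls <- do.call(rbind, lapply(placed, `[[`, "mrls"))

  # detection limits: validated LOD where consistent with the minimum
  # detected concentration, else capped so reconstructed detections are
  # detectable
  lod_of <- function(p) {
    cmin <- inc$conc_min[inc$pesticide == p]
    v <- if (!is.null(spec$validation))
      spec$validation$lod[match(p, spec$validation$pesticide)]
    else NA_real_
    if (!is.na(v) && v <= cmin) v else min(0.01, cmin)
  }
  lods <- setNames(vapply(inc$pesticide, lod_of, numeric(1)), inc$pesticide)

  conc <- conc[order(conc$commodity, conc$pesticide, conc$concentration), ]
  samples <- do.call(rbind, lapply(seq_len(nrow(occ)), function(i) {
    if (occ$n_total[i] == 0) return(NULL)
    data.frame(
      sample_id = sprintf("%s-%04d",
                          gsub("[^A-Za-z0-9]+", "_",
                               tolower(occ$product[i])),
                          seq_len(occ$n_total[i])),
      commodity = occ$product[i], group = occ$group[i],
      stringsAsFactors = FALSE)
  }))
  measurements <- do.call(rbind, lapply(seq_len(nrow(occ)), function(i) {
    sub <- conc[conc$commodity == occ$product[i], , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    ids <- samples$sample_id[samples$commodity == occ$product[i]]
    data.frame(
      sample_id = ids[seq_len(nrow(sub))],
      pesticide = sub$pesticide,
      concentration = sub$concentration,
      lod = unname(lods[sub$pesticide]),
      loq = unname(lods[sub$pesticide]) * 10 / 3.3,
      stringsAsFactors = FALSE)
  }))
  if (is.null(measurements))
    measurements <- data.frame(sample_id = character(),
                               pesticide = character(),
                               concentration = numeric(), lod = numeric(),
                               loq = numeric(), stringsAsFactors = FALSE)
  rownames(measurements) <- NULL

  mrl_table <- mrls[mrls$mrl != pls, , drop = FALSE]
  mrl_table$source <- "registered"
  rownames(mrl_table) <- NULL

  tox_table <- NULL
  if (!is.null(spec$exposure)) {
    e <- spec$exposure
    tox_table <- unique(data.frame(pesticide = e$pesticide, adi = e$adi,
                                   arfd = e$arfd, stringsAsFactors = FALSE))
    if (anyDuplicated(tox_table$pesticide) > 0)
      stop("exposure table carries conflicting ADI/ARfD for a pesticide")
    rownames(tox_table) <- NULL
  }

  fixture <- structure(
    list(samples = samples, measurements = measurements,
         mrl_table = mrl_table, tox_table = tox_table,
         exposure = spec$exposure),
    class = "survey_fixture")
  check_fixture(fixture, occ, inc, pls)
  fixture
}

# internal: verify that classifying the reconstructed dataset reproduces
# the spec marginals exactly
check_fixture <- function(fixture, occ, inc, pls) {
  cfg <- analysis_config(pls_default_mrl = pls)
  v <- classify_residues(fixture$samples, fixture$measurements,
                         fixture$mrl_table, cfg)
  o <- occurrence_by_commodity(fixture$samples, v, cfg)
  o <- o[o$product != "Total", ]
  m <- match(occ$product, o$product)
  if (!all(o$n_without[m] == occ$n_without &
           o$n_below[m] == occ$n_below &
           o$n_above[m] == occ$n_above))
    stop("internal error: reconstructed occurrence counts do not match ",
         "the spec")
  i2 <- incidence_by_pesticide(fixture$samples, v, cfg)
  m <- match(inc$pesticide, i2$pesticide)
  ok <- !anyNA(m) &&
    all(i2$n_detected[m] == inc$n_detected) &&
    all(i2$n_above[m] == inc$n_above) &&
    all(abs(i2$conc_min[m] - inc$conc_min) < 1e-9) &&
    all(abs(i2$conc_max[m] - inc$conc_max) < 1e-9)
  if (!ok)
    stop("internal error: reconstructed incidence counts do not match ",
         "the spec")
  invisible(TRUE)
}

#' @export
print.survey_fixture <- function(x, ...) {
  cat("Reconstructed monitoring dataset\n")
  cat(sprintf("  %d samples over %d commodities; %d residue measurements\n",
              nrow(x$samples), length(unique(x$samples$commodity)),
              nrow(x$measurements)))
  cat(sprintf("  %d registered MRL entries; tox table: %s\n",
              nrow(x$mrl_table),
              if (is.null(x$tox_table)) "absent"
              else paste(nrow(x$tox_table), "pesticides")))
  invisible(x)
}
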