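## Synthetic cohorts with planted block-modular connectivity and a planted
## brain-behavior association. Everything downstream (connectivity, graph
## metrics, factor analysis, association stats) is validated against the
## ground truth these generators store.

#' Default loading matrix for the synthetic 18-test battery
#'
#' Eighteen tests loading on five cognitive domains (processing speed,
#' episodic memory, executive function, working memory, language), each test
#' loading on exactly one domain. Mirrors the structure, not the numerical
#' values, of published neuropsychological batteries.
#'
#' @param loading primary loading of each test on its domain (default 0.8).
#' @return 18 x 5 matrix with test names as rownames, domains as colnames.
#' @export
default_loading_matrix <- function(loading = 0.8) {
  domains <- c("processing_speed", "episodic_memory", "executive_function",
               "working_memory", "language")
  counts <- c(4, 4, 4, 3, 3)
  tests <- unlist(mapply(function(d, k) paste0(d, "_", seq_len(k)),
                         c("ps", "em", "ef", "wm", "lg"), counts,
                         SIMPLIFY = FALSE), use.names = FALSE)
  L <- matrix(0, sum(counts), 5, dimnames = list(tests, domains))
  fac <- rep(seq_len(5), counts)
  L[cbind(seq_len(sum(counts)), fac)] <- loading
  L
}

#' Specify a synthetic cohort
#'
#' Defines the population a synthetic cohort is drawn from: per-subject
#' within- and between-network correlations (truncated normal, constrained to
#' `0 <= b < w`), a planted correlation between association-system
#' segregation and latent cognition, and a five-factor 18-test cognitive
#' battery. Association and sensory-motor systems draw independent `(w, b)`
#' pairs per subject, so the sensory-motor system is a true negative control
#' when cognition is tied to association-system segregation only.
#'
#' @param n_subjects number of subjects.
#' @param n_frames frames per subject (>= 50).
#' @param atlas a [node_atlas()] (default [default_atlas()]).
#' @param within_corr_mean,within_corr_sd population mean/sd of the
#'   within-network Pearson correlation `w`.
#' @param between_corr_mean,between_corr_sd population mean/sd of the
#'   between-network correlation `b`.
#' @param brain_behavior_r planted correlation between true
#'   association-system segregation and latent cognition `g`, in `[-1, 1]`.
#' @param n_tests,n_factors battery size (defaults 18 and 5).
#' @param loading_matrix `n_tests x n_factors` loadings; each test must load
#'   primarily on one factor.
#' @param noise_sd test-score noise standard deviation.
#' @param g_loading loading of each latent domain factor on `g`.
#' @param ct_seg_rho correlation between cortical thickness and true
#'   segregation (default 0: thickness independent of segregation).
#' @param ct_cog_rho loading of the thickness signal in the non-segregation
#'   part of `g` (default 0). Setting both rhos nonzero plants a thickness
#'   confound that partial correlation should remove.
#' @param n_sites number of (simulated) collection sites.
#' @param seed integer seed stored with the cohort.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 150, n_frames = 480,
                        atlas = default_atlas(),
                        within_corr_mean = 0.20, within_corr_sd = 0.035,
                        between_corr_mean = 0.105, between_corr_sd = 0.035,
                        brain_behavior_r = 0.25,
                        n_tests = 18, n_factors = 5,
                        loading_matrix = default_loading_matrix(),
                        noise_sd = 0.6, g_loading = sqrt(0.3),
                        ct_seg_rho = 0, ct_cog_rho = 0,
                        n_sites = 4, seed = 1L) {
  if (n_frames < 50) stop("n_frames must be >= 50")
  if (abs(brain_behavior_r) > 1) stop("|brain_behavior_r| must be <= 1")
  if (!(within_corr_mean > between_corr_mean))
    stop("expected within_corr_mean > between_corr_mean (0 <= b < w)")
  if (within_corr_mean >= 1 || between_corr_mean < 0)
    stop("correlation means must satisfy 0 <= b < w < 1")
  if (nrow(loading_matrix) != n_tests || ncol(loading_matrix) != n_factors)
    stop("loading_matrix must be n_tests x n_factors")
  primary <- apply(abs(loading_matrix), 1, which.max)
  if (any(apply(loading_matrix, 1, function(r) sum(abs(r) == max(abs(r)))) > 1))
    stop("each test must load primarily on a single factor")
  structure(list(
    n_subjects = as.integer(n_subjects), n_frames = as.integer(n_frames),
    atlas = atlas,
    within_corr_mean = within_corr_mean, within_corr_sd = within_corr_sd,
    between_corr_mean = between_corr_mean, between_corr_sd = between_corr_sd,
    brain_behavior_r = brain_behavior_r,
    n_tests = as.integer(n_tests), n_factors = as.integer(n_factors),
    loading_matrix = loading_matrix, noise_sd = noise_sd,
    g_loading = g_loading, ct_seg_rho = ct_seg_rho, ct_cog_rho = ct_cog_rho,
    n_sites = as.integer(n_sites), seed = as.integer(seed)),
    class = "cohort_spec")
}

## evaluate expr under a seed, restoring the caller's RNG state
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## truncated-normal draw by rejection (bounds lo < hi)
rtruncnorm_ <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x > lo & x < hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Block covariance with planted network structure
#'
#' Builds a node-by-node covariance with unit diagonal, `w` for off-diagonal
#' pairs within the same network, and `b` for pairs in different networks.
#' Unassigned nodes are uncorrelated with everything. If the block fill is
#' indefinite, it is repaired by clipping negative eigenvalues to zero and
#' rescaling the diagonal back to one.
#'
#' @param atlas a [node_atlas()].
#' @param w within-network correlation, in `[0, 1)`.
#' @param b between-network correlation, `0 <= b < w` (equality `b == w == 0`
#'   is allowed as the degenerate identity case).
#' @param repair apply positive-semidefinite repair if needed (default TRUE).
#' @return node x node covariance matrix with node ids as dimnames.
#' @export
make_block_covariance <- function(atlas, w, b, repair = TRUE) {
  if (w < 0 || w >= 1 || b < 0 || b >= 1) stop("w, b must lie in [0, 1)")
  if (b > w || (b == w && w > 0)) stop("need b < w (or b = w = 0)")
  wv <- stats::setNames(rep(w, length(unique(atlas$network))),
                        unique(atlas$network))
  block_covariance_(atlas, within = wv,
                    between = function(n1, n2) b, repair = repair)
}

## general block fill: `within` named per-network vector, `between` a
## function of two network labels; unassigned nodes stay uncorrelated.
## Vectorized through a network-level template matrix.
block_covariance_ <- function(atlas, within, between, repair = TRUE) {
  net <- atlas$network
  nets <- unique(net)
  k <- length(nets)
  B <- matrix(0, k, k, dimnames = list(nets, nets))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (nets[a] == "unassigned" || nets[b] == "unassigned") next
    B[a, b] <- if (a == b) within[[nets[a]]] else between(nets[a], nets[b])
  }
  idx <- match(net, nets)
  S <- B[idx, idx, drop = FALSE]
  diag(S) <- 1
  dimnames(S) <- list(atlas$node_id, atlas$node_id)
  if (repair) S <- psd_repair_(S)
  S
}

## clip negative eigenvalues to zero and rescale the diagonal to 1; a
## successful Cholesky short-circuits the eigendecomposition
psd_repair_ <- function(S, tol = 1e-10) {
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (ok) return(S)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= 0) return(S)
  v <- pmax(e$values, 0)
  R <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(R))
  d[d == 0] <- 1
  R <- R / (d %o% d)
  dimnames(R) <- dimnames(S)
  (R + t(R)) / 2
}

#' Simulate one subject's node time series
#'
#' Draws `n_frames` i.i.d. multivariate-normal frames with the given
#' covariance (eigendecomposition square root, so exact positive
#' semi-definiteness suffices).
#'
#' @param cov node x node covariance (positive semi-definite).
#' @param n_frames number of frames.
#' @param seed optional seed; the caller's RNG state is restored afterwards.
#' @return frames x nodes matrix with node ids as column names.
#' @export
simulate_subject_timeseries <- function(cov, n_frames, seed = NULL) {
  A <- tryCatch(chol(cov), error = function(err) {
    e <- eigen(cov, symmetric = TRUE)
    if (min(e$values) < -1e-8) stop("covariance is not positive semi-definite")
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  })
  with_seed_(seed, {
    X <- matrix(stats::rnorm(n_frames * ncol(cov)), n_frames, ncol(cov))
    Y <- X %*% A
    colnames(Y) <- colnames(cov)
    Y
  })
}

#' Simulate the cognitive battery given true segregation
#'
#' Latent cognition is
#' `g = r * standardize(segregation) + sqrt(1 - r^2) * noise`, so the
#' population correlation between segregation and `g` is exactly the planted
#' `brain_behavior_r`. Each of the five domain factors loads on `g` with
#' loading `g_loading`; the factor-specific disturbances are centered across
#' the five factors, so the true factor average tracks `g` exactly while
#' factor intercorrelations stay modest. Test `j` is
#' `sum_k loading[j,k] * factor_k + noise_sd * eps`.
#'
#' @param true_segregation numeric vector, one value per subject.
#' @param spec a [cohort_spec()].
#' @param seed optional seed.
#' @param confound optional standardized per-subject confound signal (e.g. a
#'   cortical-thickness deviate) entering the noise part of `g` with weight
#'   `spec$ct_cog_rho`.
#' @return list with `g`, `factors` (subjects x factors, true scores), and
#'   `tests` (subjects x tests).
#' @export
simulate_cognition <- function(true_segregation, spec, seed = NULL,
                               confound = NULL) {
  r <- spec$brain_behavior_r
  if (abs(r) > 1) stop("|brain_behavior_r| must be <= 1")
  n <- length(true_segregation)
  k <- spec$n_factors
  with_seed_(seed, {
    s <- as.numeric(scale(true_segregation))
    if (n == 1 || stats::sd(true_segregation) == 0) s <- rep(0, n)
    eps <- stats::rnorm(n)
    if (!is.null(confound) && spec$ct_cog_rho != 0) {
      rho <- spec$ct_cog_rho
      eps <- rho * confound + sqrt(1 - rho^2) * eps
    }
    g <- r * s + sqrt(1 - r^2) * eps
    c1 <- spec$g_loading
    E <- matrix(stats::rnorm(n * k), n, k)
    E <- E - rowMeans(E)                 # centered disturbances
    d <- sqrt((1 - c1^2) / ((k - 1) / k)) # var(f) = 1
    f <- c1 * g + d * E
    colnames(f) <- colnames(spec$loading_matrix)
    tests <- f %*% t(spec$loading_matrix) +
      spec$noise_sd * matrix(stats::rnorm(n * spec$n_tests), n, spec$n_tests)
    colnames(tests) <- rownames(spec$loading_matrix)
    list(g = g, factors = f, tests = tests)
  })
}

#' Simulate a full cohort
#'
#' Per subject: draws `(w, b)` for the association and sensory-motor systems
#' from truncated normals constrained to `0 <= b < w`, builds the block
#' covariance (cross-system pairs get the average of the two `b` values),
#' simulates the time series, and records the true Fisher-z scale
#' segregation `(atanh(w) - atanh(b)) / atanh(w)` per system. Cognition is
#' then generated from the association-system truth via
#' [simulate_cognition()]. Cortical thickness is drawn independently of
#' segregation unless `ct_seg_rho != 0`.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `synthetic_cohort`: `timeseries` (list of
#'   frames x nodes matrices), `subjects` (truth + covariates), `tests`
#'   (subjects x tests data.frame), `atlas`, `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  atlas <- spec$atlas
  n <- spec$n_subjects
  with_seed_(spec$seed, {
    draw_wb <- function() {
      w <- rtruncnorm_(n, spec$within_corr_mean, spec$within_corr_sd,
                       0.02, 0.97)
      b <- numeric(n)
      for (i in seq_len(n))
        b[i] <- rtruncnorm_(1, spec$between_corr_mean, spec$between_corr_sd,
                            0, w[i] - 0.01)
      list(w = w, b = b)
    }
    assoc <- draw_wb()
    sm <- draw_wb()
    seg <- (atanh(assoc$w) - atanh(assoc$b)) / atanh(assoc$w)
    seg_sm <- (atanh(sm$w) - atanh(sm$b)) / atanh(sm$w)

    sysmap <- stats::setNames(atlas$system, atlas$network)
    nets <- unique(atlas$network)
    ts <- vector("list", n)
    for (i in seq_len(n)) {
      wv <- ifelse(sysmap[nets] == "association", assoc$w[i], sm$w[i])
      names(wv) <- nets
      btw <- function(n1, n2) {
        s1 <- sysmap[[n1]]; s2 <- sysmap[[n2]]
        b1 <- if (s1 == "association") assoc$b[i] else sm$b[i]
        b2 <- if (s2 == "association") assoc$b[i] else sm$b[i]
        (b1 + b2) / 2
      }
      S <- block_covariance_(atlas, within = wv, between = btw)
      ts[[i]] <- simulate_subject_timeseries(S, spec$n_frames)
    }

    site <- sample(LETTERS[seq_len(spec$n_sites)], n, replace = TRUE)
    ct_z <- if (spec$ct_seg_rho != 0) {
      spec$ct_seg_rho * as.numeric(scale(seg)) +
        sqrt(1 - spec$ct_seg_rho^2) * stats::rnorm(n)
    } else stats::rnorm(n)
    thickness <- 2.3 + 0.15 * ct_z

    cog <- simulate_cognition(seg, spec, confound = ct_z)

    ids <- sprintf("subj_%03d", seq_len(n))
    names(ts) <- ids
    subjects <- data.frame(
      subject_id = ids, site = site, cortical_thickness = thickness,
      true_w_assoc = assoc$w, true_b_assoc = assoc$b,
      true_w_sm = sm$w, true_b_sm = sm$b,
      true_segregation = seg, true_sm_segregation = seg_sm,
      g = cog$g, stringsAsFactors = FALSE)
    tests <- data.frame(subject_id = ids, cog$tests,
                        stringsAsFactors = FALSE, check.names = FALSE)
    structure(list(timeseries = ts, subjects = subjects, tests = tests,
                   true_factors = cog$factors, atlas = atlas, spec = spec),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d subjects, %d nodes, %d frames, planted r = %.3g>\n",
              length(x$timeseries), nrow(x$atlas), x$spec$n_frames,
              x$spec$brain_behavior_r))
  invisible(x)
}

#' Write a cohort to a directory of delimited files
#'
#' Layout: `timeseries/<subject_id>.tsv` (frames x nodes, header = node
#' ids), `atlas.tsv`, `subjects.tsv`, `tests.tsv`, and `manifest.json`
#' recording the generating specification including the seed.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "timeseries"), recursive = TRUE,
             showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  for (id in names(cohort$timeseries))
    utils::write.table(cohort$timeseries[[id]],
                       file.path(dir, "timeseries", paste0(id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  wt(as.data.frame(cohort$atlas), "atlas.tsv")
  wt(cohort$subjects, "subjects.tsv")
  wt(cohort$tests, "tests.tsv")
  man <- unclass(cohort$spec)
  man$atlas <- NULL
  man$test_names <- rownames(man$loading_matrix)
  man$factor_names <- colnames(man$loading_matrix)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir cohort directory.
#' @return a `synthetic_cohort` (the `spec` is rebuilt from the manifest).
#' @export
read_cohort <- function(dir) {
  atlas_df <- utils::read.delim(file.path(dir, "atlas.tsv"))
  atlas <- node_atlas(atlas_df$node_id, atlas_df$network, atlas_df$system)
  subjects <- utils::read.delim(file.path(dir, "subjects.tsv"))
  tests <- utils::read.delim(file.path(dir, "tests.tsv"), check.names = FALSE)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  L <- matrix(unlist(man$loading_matrix), man$n_tests, man$n_factors)
  dimnames(L) <- list(man$test_names, man$factor_names)
  spec <- cohort_spec(
    n_subjects = man$n_subjects, n_frames = man$n_frames, atlas = atlas,
    within_corr_mean = man$within_corr_mean, within_corr_sd = man$within_corr_sd,
    between_corr_mean = man$between_corr_mean, between_corr_sd = man$between_corr_sd,
    brain_behavior_r = man$brain_behavior_r, n_tests = man$n_tests,
    n_factors = man$n_factors, loading_matrix = L, noise_sd = man$noise_sd,
    g_loading = man$g_loading, ct_seg_rho = man$ct_seg_rho,
    ct_cog_rho = man$ct_cog_rho, n_sites = man$n_sites, seed = man$seed)
  ids <- subjects$subject_id
  ts <- lapply(ids, function(id)
    as.matrix(utils::read.delim(file.path(dir, "timeseries",
                                          paste0(id, ".tsv")),
                                check.names = FALSE)))
  names(ts) <- ids
  structure(list(timeseries = ts, subjects = subjects, tests = tests,
                 true_factors = NULL, atlas = atlas, spec = spec),
            class = "synthetic_cohort")
}
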