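#' Construct a FRAPTrace
#'
#' @param times frame times in seconds (strictly increasing).
#' @param roi bleach-ROI intensity per frame (counts).
#' @param reference unbleached reference-region intensity per frame.
#' @param background background intensity (scalar or per frame).
#' @param nPre number of pre-bleach frames.
#' @return a \linkS4class{FRAPTrace}.
#' @export
frapTrace <- function(times, roi, reference, background = 0, nPre = 10L) {
    new("FRAPTrace", times = as.numeric(times), roi = as.numeric(roi),
        reference = as.numeric(reference),
        background = as.numeric(background), nPre = as.integer(nPre))
}

#' Double-normalize a FRAP recovery trace
#'
#' Corrects the bleach-ROI intensity for background and for acquisition
#' fading (shared photobleaching during recording) using the unbleached
#' reference region:
#' \deqn{I_{norm}(t) = \frac{roi(t) - bg}{ref(t) - bg} \cdot
#'       \frac{\overline{ref_{pre}} - bg}{\overline{roi_{pre}} - bg},}
#' then rescales so the pre-bleach mean is exactly 1. Any fading shared
#' multiplicatively by ROI and reference cancels.
#'
#' @param trace a \linkS4class{FRAPTrace}.
#' @return data.frame with columns \code{time}, \code{intensity} (the
#'   normalized curve over all frames) and \code{phase}
#'   ("pre"/"post").
#' @export
normalizeTrace <- function(trace) {
    validObject(trace)
    bg <- trace@background
    roiC <- trace@roi - bg
    refC <- trace@reference - bg
    if (any(refC <= 0))
        stop("reference intensity at or below background", call. = FALSE)
    pre <- seq_len(trace@nPre)
    .stopIfNot(mean(roiC[pre]) > 0, "pre-bleach ROI mean not above background")
    inorm <- (roiC / refC) * (mean(refC[pre]) / mean(roiC[pre]))
    inorm <- inorm / mean(inorm[pre])
    data.frame(time = trace@times, intensity = inorm,
               phase = rep(c("pre", "post"),
                           c(trace@nPre, length(trace@times) - trace@nPre)))
}

# Profile fit of I(t) = I0 + A (1 - exp(-t/tau)) over post-bleach times
# (t measured from the first post-bleach frame): for fixed tau the model is
# linear in (I0, A), so tau is found by 1-D minimization of the profiled
# RSS on a log scale, which is robust and derivative-free.
.fitExpRecovery <- function(t, y) {
    tspan <- max(t) - min(t)
    t0 <- t - t[1]
    rssAt <- function(logTau) {
        tau <- exp(logTau)
        b <- 1 - exp(-t0 / tau)
        fit <- stats::lm.fit(cbind(1, b), y)
        sum(fit$residuals^2)
    }
    opt <- stats::optimize(rssAt,
                           lower = log(tspan * 1e-4),
                           upper = log(tspan * 1e3), tol = 1e-10)
    tau <- exp(opt$minimum)
    b <- 1 - exp(-t0 / tau)
    cf <- stats::lm.fit(cbind(1, b), y)$coefficients
    list(tau = tau, I0 = cf[1], A = cf[2], rss = opt$objective)
}

#' Fit a single-exponential recovery to a normalized FRAP curve
#'
#' Least-squares fit of \eqn{I(t) = I_0 + A (1 - e^{-t/\tau})} to the
#' post-bleach frames of a normalized trace. The half-time is
#' \eqn{T/2 = \tau \ln 2}. The mobile fraction is
#' \eqn{(plateau - I_{bleach}) / (1 - I_{bleach})} with \eqn{I_{bleach}}
#' the first post-bleach value and \eqn{plateau = I_0 + A}; the immobile
#' fraction is its complement. A model-free half-time (first crossing of
#' the midpoint between bleach depth and the mean of the last 30 frames)
#' is attached as a cross-check.
#'
#' @param curve data.frame from \code{\link{normalizeTrace}}, or a numeric
#'   vector of normalized intensities (then supply \code{times}).
#' @param times frame times when \code{curve} is a bare vector.
#' @param nPre number of pre-bleach frames when \code{curve} is a bare
#'   vector (taken from the \code{phase} column otherwise).
#' @return a \linkS4class{FRAPFit}.
#' @examples
#' t <- seq(0, 120, by = 0.555)
#' y <- 0.2 + 0.5 * (1 - exp(-t / 20))
#' fit <- fitRecovery(y, times = t, nPre = 0)
#' fit@tHalf / fit@tau  # log(2)
#' @export
fitRecovery <- function(curve, times = NULL, nPre = NULL) {
    if (is.data.frame(curve)) {
        times <- curve$time
        nPre <- sum(curve$phase == "pre")
        curve <- curve$intensity
    }
    post <- if (nPre > 0) -(seq_len(nPre)) else seq_along(curve)
    y <- curve[post]
    t <- times[post]
    .stopIfNot(length(y) >= 20, "need >= 20 post-bleach points")
    fit <- .fitExpRecovery(t, y)
    plateau <- unname(fit$I0 + fit$A)
    iBleach <- y[1]
    if (plateau < iBleach - 1e-9)
        stop("non-physical fit: plateau below bleach depth", call. = FALSE)
    denom <- 1 - iBleach
    # no visible bleach depth: everything recovered instantaneously
    mobile <- if (denom < 1e-9) 1 else (plateau - iBleach) / denom
    mobile <- min(max(mobile, 0), 1)
    lateP <- mean(utils::tail(y, 30L))
    mid <- (iBleach + lateP) / 2
    crossIdx <- which(y >= mid)[1]
    tHalfEmp <- if (is.na(crossIdx)) NA_real_ else t[crossIdx] - t[1]
    new("FRAPFit", tHalf = fit$tau * log(2), tau = fit$tau,
        immobileFraction = 1 - mobile, mobileFraction = mobile,
        plateau = plateau, bleachDepth = iBleach,
        tHalfEmpirical = tHalfEmp, rss = fit$rss)
}

#' Compare FRAP parameters between two groups
#'
#' Two-sample Student t-test (equal variance by default, Welch optional) on
#' the recovery half-time and on the immobile fraction between two groups
#' of fitted traces, e.g. high- versus low-fluorescence-intensity bleach
#' regions.
#'
#' @param fitsA,fitsB lists of \linkS4class{FRAPFit} objects (>= 2 each).
#' @param welch use the Welch unequal-variance variant.
#' @return data.frame with one row per quantity (t_half, immobile_fraction):
#'   group means and the p-value.
#' @export
compareGroups <- function(fitsA, fitsB, welch = FALSE) {
    .stopIfNot(length(fitsA) >= 2 && length(fitsB) >= 2,
               "need >= 2 fits per group")
    pull <- function(fits, slotName)
        vapply(fits, function(f) slot(f, slotName), numeric(1))
    one <- function(slotName, label) {
        a <- pull(fitsA, slotName); b <- pull(fitsB, slotName)
        if (stats::var(c(a - mean(a), b - mean(b))) == 0 && !welch)
            stop("zero pooled variance", call. = FALSE)
        ht <- stats::t.test(a, b, var.equal = !welch)
        data.frame(quantity = label, mean_a = mean(a), mean_b = mean(b),
                   p_value = ht$p.value, stringsAsFactors = FALSE)
    }
    rbind(one("tHalf", "t_half"),
          one("immobileFraction", "immobile_fraction"))
}

#' Simulate a FRAP trace with known recovery parameters
#'
#' Generates 10 pre-bleach and 300 post-bleach frames at 0.555-second
#' intervals: a single-exponential recovery with time constant \code{tau}
#' and the given immobile fraction, an optional multiplicative acquisition
#' fading applied to ROI and reference alike, Gaussian noise, and a
#' constant background. Deterministic for a fixed seed.
#'
#' @param tau recovery time constant in seconds.
#' @param immobile immobile fraction in [0, 1].
#' @param noiseSd Gaussian noise SD relative to the pre-bleach signal.
#' @param fadingRate exponential fading rate (1/s) shared by ROI and
#'   reference.
#' @param seed integer seed.
#' @param bleachDepth normalized intensity immediately after the bleach.
#' @param nPre,nPost frame counts before/after the bleach.
#' @param dt frame interval in seconds.
#' @return a \linkS4class{FRAPTrace}.
#' @export
simulateFrap <- function(tau, immobile, noiseSd = 0, fadingRate = 0,
                         seed = 1, bleachDepth = 0.2, nPre = 10L,
                         nPost = 300L, dt = 0.555) {
    .stopIfNot(tau > 0, "tau must be positive")
    .stopIfNot(immobile >= 0 && immobile <= 1, "immobile must be in [0, 1]")
    n <- nPre + nPost
    times <- (seq_len(n) - 1) * dt
    tPost <- times[(nPre + 1):n] - times[nPre + 1]
    roiSig <- 1000
    refSig <- 800
    bg <- 50
    rec <- bleachDepth + (1 - immobile) * (1 - bleachDepth) *
        (1 - exp(-tPost / tau))
    roi <- c(rep(roiSig, nPre), roiSig * rec)
    ref <- rep(refSig, n)
    fade <- exp(-fadingRate * times)
    roi <- roi * fade
    ref <- ref * fade
    if (noiseSd > 0) {
        .withSeed(seed, {
            roi <- roi + stats::rnorm(n, 0, noiseSd * roiSig)
            ref <- ref + stats::rnorm(n, 0, noiseSd * refSig)
        })
    }
    frapTrace(times, roi + bg, ref + bg, background = bg, nPre = nPre)
}

#' Read FRAP traces from CSV
#'
#' Expects columns \code{time_s}, \code{roi}, \code{reference},
#' \code{background} and \code{phase} ("pre"/"post"); an optional
#' \code{trace} column separates multiple traces and an optional
#' \code{group} column is carried through as names.
#'
#' @param path CSV file path.
#' @return named list of \linkS4class{FRAPTrace} objects.
#' @export
readFrapTraces <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("time_s", "roi", "reference", "background", "phase")
    .stopIfNot(all(need %in% names(df)),
               paste("CSV must contain columns:", paste(need, collapse = ", ")))
    ids <- if ("trace" %in% names(df)) df$trace else rep("trace_1", nrow(df))
    out <- lapply(split(df, ids), function(g) {
        g <- g[order(g$time_s), ]
        frapTrace(g$time_s, g$roi, g$reference,
                  background = g$background[1],
                  nPre = sum(g$phase == "pre"))
    })
    out
}
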