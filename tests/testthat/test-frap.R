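test_that("simulated traces have the published frame structure", {
    tr <- simulateFrap(tau = 20, immobile = 0.3, seed = 1)
    expect_length(tr@times, 310)          # 10 pre + 300 post
    expect_equal(tr@nPre, 10L)
    expect_equal(unique(round(diff(tr@times), 6)), 0.555)
})

test_that("normalization is exact for constant and fading-only traces", {
    t <- (0:99) * 0.555
    flat <- frapTrace(t, rep(1000, 100), rep(800, 100), background = 50,
                      nPre = 10)
    expect_equal(normalizeTrace(flat)$intensity, rep(1, 100))
    # pure shared fading cancels exactly
    fade <- 1 - 0.002 * t
    faded <- frapTrace(t, 50 + 950 * fade, 50 + 750 * fade,
                       background = 50, nPre = 10)
    expect_equal(normalizeTrace(faded)$intensity, rep(1, 100),
                 tolerance = 1e-12)
})

test_that("normalization recovers a constructed recovery curve", {
    t <- (0:309) * 0.555
    nPre <- 10
    rec <- c(rep(1, nPre),
             0.2 + 0.5 * (1 - exp(-(t[(nPre + 1):310] - t[nPre + 1]) / 20)))
    ref <- rep(700, 310)
    tr <- frapTrace(t, 30 + ref * rec, 30 + ref, background = 30,
                    nPre = nPre)
    nc <- normalizeTrace(tr)
    expect_lt(max(abs(nc$intensity - rec)), 1e-9)
    expect_error(normalizeTrace(frapTrace(t, ref, rep(20, 310),
                                          background = 30, nPre = 10)),
                 "reference")
})

test_that("exponential fit recovers closed-form parameters", {
    t <- seq(0, 166, by = 0.555)
    y <- 0.2 + 0.5 * (1 - exp(-t / 20))
    fit <- fitRecovery(y, times = t, nPre = 0)
    expect_equal(fit@tau, 20, tolerance = 1e-6)
    expect_equal(fit@tHalf, 20 * log(2), tolerance = 1e-6)
    expect_equal(fit@plateau, 0.7, tolerance = 1e-6)
    expect_equal(fit@mobileFraction, 0.625, tolerance = 1e-6)
    expect_equal(fit@immobileFraction, 0.375, tolerance = 1e-6)
    expect_equal(fit@tHalf / fit@tau, log(2))
})

test_that("edge cases: instantaneous recovery and no recovery", {
    t <- seq(0, 30, by = 0.5)
    full <- fitRecovery(rep(1, length(t)), times = t, nPre = 0)
    expect_equal(full@immobileFraction, 0)
    flat <- fitRecovery(rep(0.2, length(t)), times = t, nPre = 0)
    expect_equal(flat@mobileFraction, 0)
    expect_equal(flat@immobileFraction, 1)
})

test_that("noiseless round trip recovers tau and immobile to 4 significant figures", {
    for (par in list(c(10, 0.2), c(20, 0.375), c(45, 0.6))) {
        tr <- simulateFrap(tau = par[1], immobile = par[2], noiseSd = 0,
                           fadingRate = 0.001, seed = 2)
        fit <- fitRecovery(normalizeTrace(tr))
        expect_lt(abs(fit@tau / par[1] - 1), 5e-4)
        expect_lt(abs(fit@immobileFraction - par[2]), 5e-4 * par[2])
    }
})

test_that("the profile fit agrees with an independent nls fit", {
    tr <- simulateFrap(tau = 18, immobile = 0.3, noiseSd = 0.02, seed = 6)
    nc <- normalizeTrace(tr)
    post <- nc[nc$phase == "post", ]
    t0 <- post$time - post$time[1]
    ref <- minpack.lm::nlsLM(
        intensity ~ I0 + A * (1 - exp(-t0 / tau)),
        data = cbind(post, t0 = t0),
        start = list(I0 = 0.2, A = 0.5, tau = 10))
    fit <- fitRecovery(nc)
    expect_equal(fit@tau, coef(ref)[["tau"]], tolerance = 1e-4)
    expect_equal(fit@plateau, coef(ref)[["I0"]] + coef(ref)[["A"]],
                 tolerance = 1e-4)
})

test_that("tau is recovered within 10% per trace and <5% bias under 2% noise", {
    taus <- vapply(1:20, function(s) {
        tr <- simulateFrap(tau = 20, immobile = 0.375, noiseSd = 0.02,
                           seed = s)
        fitRecovery(normalizeTrace(tr))@tau
    }, numeric(1))
    expect_true(all(abs(taus / 20 - 1) < 0.10))
    expect_lt(abs(mean(taus) / 20 - 1), 0.05)
})

test_that("the model-free half-time tracks the fitted one", {
    tr <- simulateFrap(tau = 25, immobile = 0.3, noiseSd = 0, seed = 2)
    fit <- fitRecovery(normalizeTrace(tr))
    expect_lt(abs(fit@tHalfEmpirical / fit@tHalf - 1), 0.15)
})

test_that("group comparison: identical groups p = 1, separated groups p < 0.001", {
    mk <- function(tau, n, seedOff = 0, noise = 0.01)
        lapply(seq_len(n), function(i)
            fitRecovery(normalizeTrace(simulateFrap(
                tau = tau, immobile = 0.3, noiseSd = noise,
                seed = i + seedOff))))
    a <- mk(15, 5)
    cmpSame <- compareGroups(a, a)
    expect_equal(cmpSame$p_value, c(1, 1))
    b10 <- mk(10, 10, seedOff = 100)
    b40 <- mk(40, 10, seedOff = 200)
    cmp <- compareGroups(b10, b40)
    expect_lt(cmp$p_value[cmp$quantity == "t_half"], 0.001)
    expect_error(compareGroups(a, a[1]), ">= 2 fits")
})

test_that("FRAP CSV round trip preserves traces and groups", {
    path <- withr::local_tempfile(fileext = ".csv")
    tr1 <- simulateFrap(tau = 12, immobile = 0.2, noiseSd = 0.01, seed = 4)
    tr2 <- simulateFrap(tau = 30, immobile = 0.5, noiseSd = 0.01, seed = 5)
    df <- rbind(
        data.frame(trace = "hfi_1", time_s = tr1@times, roi = tr1@roi,
                   reference = tr1@reference, background = tr1@background,
                   phase = rep(c("pre", "post"), c(10, 300))),
        data.frame(trace = "lfi_1", time_s = tr2@times, roi = tr2@roi,
                   reference = tr2@reference, background = tr2@background,
                   phase = rep(c("pre", "post"), c(10, 300))))
    write.csv(df, path, row.names = FALSE)
    traces <- readFrapTraces(path)
    expect_named(traces, c("hfi_1", "lfi_1"))
    fit1 <- fitRecovery(normalizeTrace(traces$hfi_1))
    expect_lt(abs(fit1@tau / 12 - 1), 0.1)
})
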