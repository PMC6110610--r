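# Shared fixtures, built once per test run. Everything is generated in
# code; sizes are kept small so the whole suite stays desk-scale.

choP <- choPreset()
s2P <- s2Preset()

# proximal CHO blade, 24 nm, canonical tilt
fixtureBlade <- local({
  buildBlade(bladeSpecForPreset(choP, "proximal"), 24,
             tilt = choP@bladeTiltProximal, seed = 1)
})

fixtureBladeDistal <- local({
  buildBlade(bladeSpecForPreset(choP, "distal"), 24,
             tilt = choP@bladeTiltDistal, seed = 1)
})

fixtureBladeFly <- local({
  buildBlade(bladeSpecForPreset(s2P, "fly"), 24,
             tilt = s2P@bladeTiltProximal, seed = 1)
})

# ideal rasterized proximal blade reference (52^3 at 1.5 nm)
fixtureRef <- suppressWarnings(rasterize(fixtureBlade, 1.5, box = rep(52, 3)))

cylMask <- function(box = 52, radius = 22, hz = 11)
  centriotome:::softCylMask(rep(box, 3), radius = radius, hz = hz)

expectEqualRel <- function(x, y, tol) expect_lt(abs(x - y) / abs(y), tol)
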