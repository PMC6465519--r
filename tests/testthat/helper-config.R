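# Small-grid configurations used across the suite. 32^3 at 3 mm keeps the
# phantom's white matter (~90 ml) safely above the lesion-volume cap; 24^3
# at 4 mm is the fastest grid that still has a lesion-bearing WM interior.

testConfig <- function(..., gridShape = 32L, voxelSizeMM = 3,
                       nPerGroup = 6L, femaleCount = 3L, seed = 1L) {
  generatorConfig(gridShape = gridShape, voxelSizeMM = voxelSizeMM,
                  nPerGroup = nPerGroup, femaleCount = femaleCount,
                  seed = seed, ...)
}

# all nuisance processes disabled: renders are exactly piecewise constant
cleanConfig <- function(...) {
  testConfig(noiseSd = 0, gainSdT1w = 0, gainSdT2w = 0, biasAmplitude = 0, ...)
}

firstSubject <- function(config, group = "MS") {
  tab <- generateSubjectTable(config)
  tab[tab$group == group, ][1, ]
}
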