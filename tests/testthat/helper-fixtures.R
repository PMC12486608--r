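# Shared fixtures: tiny grids and a fast, small-scale synthetic design
# used wherever the full 24^3 x 30-subject validation scale is not the
# point of the test.

tinyGrid <- function(n = 9, voxelMm = 3) {
  coordnet::volumeGrid(rep(n, 3), voxelMm = voxelMm)
}

fullMask <- function(grid) {
  coordnet::brainMask(array(TRUE, coordnet::gridDim(grid)), grid)
}

# small world: 16^3 grid, 2 planted networks, 6 subjects x 80 volumes
smallDesign <- function(masterSeed = 7, ...) {
  coordnet::syntheticDesign(
    gridDim = c(16, 16, 16), voxelMm = 3, nNetworks = 2,
    nSubjects = 6, nVolumes = 80, trSeconds = 2, amplitude = 0.3,
    noiseSd = 1, spikeProb = 0.1, brainRadiusMm = 21,
    networkSemiAxesMm = c(6, 9, 6), networkRingMm = 11,
    tissueZMm = 13, masterSeed = masterSeed, ...)
}

smallWorld <- function(design = smallDesign()) {
  coordnet::makeAtlas(design)
}

smallProvider <- function(design, world) {
  force(design); force(world)
  function(i) {
    s <- coordnet::simulateSubject(design, world,
                                   coordnet::deriveSeed(design$masterSeed,
                                                        i))
    s[c("bold", "motion")]
  }
}

# write a minimal contrast table and return its path
writeTestTable <- function(lines, sep = ",") {
  tf <- tempfile(fileext = ".csv")
  writeLines(lines, tf)
  tf
}

contrastHeader <- "study,contrast,space,x,y,z,direction,sex,age_group,state"
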