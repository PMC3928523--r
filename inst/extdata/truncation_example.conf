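# Artificial selection experiment: truncation selection on a polygenic
# trait.  The top 20% of individuals by trait value reproduce each
# generation.

Chromosomes chroms
    lengths = 10000000

Trajectory_Constant popsize
    value = 200

Demography demo
    populations = 1
    generations = 10
    size = popsize
    migration = none

RecombinationMap_Uniform map
    rate = 1

Distribution_Uniform qtl_positions
    low = 0
    high = 10000000

Distribution_Normal qtl_effects
    mean = 0
    sd = 0.25

Locus q1
    chromosome = 1
    position = qtl_positions
    frequency = 0.5

Locus q2
    chromosome = 1
    position = qtl_positions
    frequency = 0.5

Locus q3
    chromosome = 1
    position = qtl_positions
    frequency = 0.5

QTL qtl1
    locus = q1
    effect = qtl_effects

QTL qtl2
    locus = q2
    effect = qtl_effects

QTL qtl3
    locus = q3
    effect = qtl_effects

Trait yield
    qtls = qtl1 qtl2 qtl3
    heritability = 0.5

FitnessFunction_Truncation select_top
    trait = yield
    proportion = 0.2
    direction = high

Simulator sim
    seed = 7
    chromosomes = chroms
    demography = demo
    maps = map
    loci = q1 q2 q3
    traits = yield
    fitness = select_top
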