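"""Coalescent genotype backend.

Reads a JSON batch description and, for every replicate, simulates a
two-population split demography with msprime, superimposes infinite-sites
mutations, and writes the sampled diploid genotype matrices to disk in a
compact raw format read back by the R side.

Batch JSON schema:
  {
    "out_dir": str,
    "replicates": [
      {"id": int, "seed": int, "N0": float, "N": float, "T": float,
       "m": float, "g": float, "genome_length_bp": float,
       "recomb_rate_per_bp": float, "mu": float,
       "n_ref": int, "n_bot": int, "trees_path": str | null},
      ...
    ]
  }

Per replicate <id> the script writes into out_dir:
  rep<id>.meta  text: "<n_sites> <n_ref> <n_bot>"
  rep<id>.pos   text: one float position per line (all mutated sites)
  rep<id>.geno  raw uint8, (n_ref + n_bot) x n_sites derived-allele counts,
                row-major, reference individuals first

Filtering to sites segregating in the reference sample is done in R; the
full mutated site set is exported here.
"""

import json
import math
import sys

import msprime
import numpy as np

# Mutation seed is derived from the ancestry seed with a fixed multiplicative
# step so that consecutive user seeds cannot collide across the two layers.
MUT_SEED_MOD = 2**31 - 1


def mutation_seed(seed):
    return (seed * 48271) % MUT_SEED_MOD + 1


def build_demography(N0, N, T, m, g):
    """Two populations splitting T generations ago from an ancestor of size N0.

    The bottlenecked population is founded at diploid size N and grows
    exponentially forward in time at rate g, so its present-day size is
    N * exp(g * T). Forward-time migration moves a fraction m of the
    bottlenecked population from the reference population each generation,
    which in the backward-time convention is lineage movement BOT -> REF.
    """
    d = msprime.Demography()
    d.add_population(name="REF", initial_size=N0)
    d.add_population(name="BOT", initial_size=N * math.exp(g * T), growth_rate=g)
    d.add_population(name="ANC", initial_size=N0)
    if m > 0:
        d.set_migration_rate(source="BOT", dest="REF", rate=m)
    d.add_population_split(time=T, derived=["REF", "BOT"], ancestral="ANC")
    return d


def simulate_one(rep):
    T = rep["T"]
    n_ref = int(rep["n_ref"])
    n_bot = int(rep["n_bot"])
    seed = int(rep["seed"])
    if T > 0:
        demography = build_demography(
            rep["N0"], rep["N"], T, rep["m"], rep["g"])
        samples = {"REF": n_ref, "BOT": n_bot}
    else:
        # Degenerate split at the present: both samples come from one
        # panmictic population of size N0.
        demography = msprime.Demography()
        demography.add_population(name="ANC", initial_size=rep["N0"])
        samples = {"ANC": n_ref + n_bot}
    ts = msprime.sim_ancestry(
        samples=samples,
        demography=demography,
        sequence_length=rep["genome_length_bp"],
        recombination_rate=rep["recomb_rate_per_bp"],
        ploidy=2,
        random_seed=seed,
    )
    # Continuous positions + binary model = infinite sites, every mutation at
    # a new site, with no restriction on when mutations occur.
    ts = msprime.sim_mutations(
        ts,
        rate=rep["mu"],
        random_seed=mutation_seed(seed),
        model=msprime.BinaryMutationModel(),
        discrete_genome=False,
    )
    return ts


def write_one(ts, rep, out_dir):
    n_ref = int(rep["n_ref"])
    n_bot = int(rep["n_bot"])
    G = ts.genotype_matrix()  # n_sites x n_haplotypes, 0/1
    n_sites = G.shape[0]
    if n_sites > 0:
        counts = G[:, 0::2] + G[:, 1::2]  # n_sites x n_individuals
        M = np.ascontiguousarray(counts.T, dtype=np.uint8)
    else:
        M = np.zeros((n_ref + n_bot, 0), dtype=np.uint8)
    positions = ts.tables.sites.position
    rid = rep["id"]
    with open(f"{out_dir}/rep{rid}.meta", "w") as fh:
        fh.write(f"{n_sites} {n_ref} {n_bot}\n")
    np.savetxt(f"{out_dir}/rep{rid}.pos", positions, fmt="%.17g")
    M.tofile(f"{out_dir}/rep{rid}.geno")
    if rep.get("trees_path"):
        ts.dump(rep["trees_path"])


def main(argv):
    if len(argv) != 2:
        sys.exit("usage: msprime_backend.py <batch.json>")
    with open(argv[1]) as fh:
        batch = json.load(fh)
    out_dir = batch["out_dir"]
    for rep in batch["replicates"]:
        ts = simulate_one(rep)
        write_one(ts, rep, out_dir)


if __name__ == "__main__":
    main(sys.argv)
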