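"""Solve a batch of minimum set cover problems with HiGHS.

Reads a JSON list of problems (c, b, sparse triplets i/j/v, n_units, gap,
time_limit) from argv[1] and writes a JSON list of solutions (status, x,
objective, gap) to argv[2]. Each problem is:

    minimize c.x  subject to  A x >= b,  x binary.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import LinearConstraint, milp


def solve_one(p):
    c = np.atleast_1d(np.asarray(p["c"], dtype=float))
    b = np.atleast_1d(np.asarray(p["b"], dtype=float))
    n = int(p["n_units"])
    i = np.atleast_1d(np.asarray(p["i"], dtype=int))
    j = np.atleast_1d(np.asarray(p["j"], dtype=int))
    v = np.atleast_1d(np.asarray(p["v"], dtype=float))
    A = sparse.csr_matrix((v, (i, j)), shape=(len(b), n))
    options = {"mip_rel_gap": float(p.get("gap", 0.0))}
    tl = float(p.get("time_limit", -1))
    if tl > 0:
        options["time_limit"] = tl
    res = milp(
        c=c,
        constraints=[LinearConstraint(A, lb=b, ub=np.inf)],
        integrality=np.ones(n),
        bounds=(0, 1),
        options=options,
    )
    if res.status == 2 or res.x is None:  # infeasible
        return {"status": "infeasible", "x": None, "objective": None,
                "gap": None}
    x = np.round(res.x).astype(int)
    gap = float(getattr(res, "mip_gap", 0.0) or 0.0)
    return {
        "status": "optimal" if res.status == 0 else "feasible_gap",
        "x": x.tolist(),
        "objective": float(np.dot(c, x)),
        "gap": gap,
    }


def main():
    with open(sys.argv[1]) as fh:
        problems = json.load(fh)
    out = [solve_one(p) for p in problems]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
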