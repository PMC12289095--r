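"""Batch LP oracle: reads a JSON list of problems, solves each with
scipy's HiGHS backend, writes a JSON list of {status, objective}.

Each problem: {"obj": [...], "rows": [[...]], "rl": [...], "ru": [...],
"lb": [...], "ub": [...]} maximizing obj'v subject to rl <= rows.v <= ru
and lb <= v <= ub. Magnitudes >= 1e29 encode infinity.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog

BIG = 1e29


def fin(x):
    x = np.asarray(x, dtype=float)
    x[x >= BIG] = np.inf
    x[x <= -BIG] = -np.inf
    return x


def solve(p):
    obj = np.asarray(p["obj"], dtype=float)
    A = np.asarray(p["rows"], dtype=float).reshape(len(p["rl"]), len(obj))
    rl, ru = fin(p["rl"]), fin(p["ru"])
    lb, ub = fin(p["lb"]), fin(p["ub"])
    eq = rl == ru
    A_eq = A[eq] if eq.any() else None
    b_eq = ru[eq] if eq.any() else None
    A_ub, b_ub = [], []
    for i in np.where(~eq)[0]:
        if np.isfinite(ru[i]):
            A_ub.append(A[i])
            b_ub.append(ru[i])
        if np.isfinite(rl[i]):
            A_ub.append(-A[i])
            b_ub.append(-rl[i])
    res = linprog(
        -obj,
        A_ub=np.asarray(A_ub) if A_ub else None,
        b_ub=np.asarray(b_ub) if b_ub else None,
        A_eq=A_eq,
        b_eq=b_eq,
        bounds=list(zip(lb, ub)),
        method="highs",
    )
    status = {0: "optimal", 2: "infeasible", 3: "unbounded"}.get(res.status, "failed")
    return {"status": status, "objective": -res.fun if res.status == 0 else None}


def main():
    with open(sys.argv[1]) as fh:
        problems = json.load(fh)
    out = [solve(p) for p in problems]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
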