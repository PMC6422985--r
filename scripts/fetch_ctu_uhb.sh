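#!/usr/bin/env bash
# Download the open-access CTU-UHB intrapartum cardiotocography database
# (552 WFDB records with umbilical-artery pH in the header comments) from
# PhysioNet, for full-scale replication. Nothing in the package or its tests
# calls this script; the library itself never touches the network.
#
# Usage: scripts/fetch_ctu_uhb.sh [target_dir]
set -euo pipefail
TARGET="${1:-data/ctu-uhb}"
mkdir -p "$TARGET"
wget -r -N -c -np -nH --cut-dirs=3 -P "$TARGET" \
  https://physionet.org/files/ctu-uhb-ctgdb/1.0.0/
echo "records in $TARGET; read one with fetalrp::read_physionet_record()"
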