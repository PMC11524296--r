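method,trait,wavelength_nm
spa,lcc,873.5
spa,lcc,1387.6
spa,lcc,1394.2
spa,lcc,1425.7
spa,lcc,1577.4
spa,lcc,1651.4
spa,lcc,1671.1
spa,lcc,1689.2
spa,lcc,1697.4
spa,lcc,1702.3
spa,lwc,873.5
spa,lwc,895.3
spa,lwc,917
spa,lwc,968.8
spa,lwc,1289.9
spa,lwc,1389.3
spa,lwc,1394.2
spa,lwc,1575.7
spa,lwc,1653
spa,lwc,1689.2
spa,lwc,1695.8
spa,lwc,1700.7
spa,lwc,1702.3
cars,lcc,880.2
cars,lcc,881.9
cars,lcc,883.6
cars,lcc,885.3
cars,lcc,890.3
cars,lcc,953.8
cars,lcc,955.5
cars,lcc,957.1
cars,lcc,958.8
cars,lcc,962.2
cars,lcc,967.2
cars,lcc,1137.2
cars,lcc,1138.8
cars,lcc,1142.2
cars,lcc,1152.2
cars,lcc,1153.8
cars,lcc,1158.8
cars,lcc,1162.1
cars,lcc,1213.6
cars,lcc,1225.3
cars,lcc,1231.9
cars,lcc,1233.6
cars,lcc,1424
cars,lcc,1430.6
cars,lcc,1432.3
cars,lcc,1433.9
cars,lcc,1435.6
cars,lcc,1542.8
cars,lcc,1544.4
cars,lcc,1546.1
cars,lcc,1547.7
cars,lcc,1549.4
cars,lcc,1552.7
cars,lcc,1557.6
cars,lcc,1559.3
cars,lcc,1560.9
cars,lcc,1565.9
cars,lcc,1567.5
cars,lcc,1574.1
cars,lcc,1580.7
cars,lcc,1662.9
cars,lcc,1664.6
cars,lcc,1666.2
cars,lcc,1669.5
cars,lcc,1671.1
cars,lcc,1672.8
cars,lcc,1674.4
cars,lcc,1676.1
cars,lcc,1677.7
cars,lcc,1684.3
cars,lcc,1699
cars,lcc,1700.7
cars,lcc,1702.3
cars,lwc,881.9
cars,lwc,883.6
cars,lwc,885.3
cars,lwc,958.8
cars,lwc,1213.6
cars,lwc,1231.9
cars,lwc,1233.6
cars,lwc,1427.3
cars,lwc,1433.9
cars,lwc,1435.6
cars,lwc,1440.5
cars,lwc,1549.4
cars,lwc,1552.7
cars,lwc,1554.3
cars,lwc,1556
cars,lwc,1557.6
cars,lwc,1560.9
cars,lwc,1562.6
cars,lwc,1565.9
cars,lwc,1567.5
cars,lwc,1580.7
cars,lwc,1664.6
cars,lwc,1669.5
cars,lwc,1671.1
cars,lwc,1672.8
cars,lwc,1674.4
cars,lwc,1676.1
cars,lwc,1700.7
cars,lwc,1702.3
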