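rank,CAR,PXR,AR,PPARa,PPARg,PPARd,RORgt
1,662-28-2,5366-99-4,306-91-2,548470-06-0,NOCAS_1026885,21674-38-4,862130-96-9
2,306-91-2,61778-79-8,86630-50-4,547748-28-7,57589-85-2,57101-59-4,86630-50-4
3,307-08-4,548470-06-0,558-64-5,21674-38-4,151707-04-9,347838-21-5,88951-08-0
4,118914-94-6,NOCAS_871520,119107-96-9,NOCAS_1027003,749924-57-0,25761-65-3,NOCAS_1026885
5,558-64-5,347838-21-5,61855-74-1,1075687-38-5,919293-76-8,230295-10-0,2663-96-9
6,118914-93-5,NOCAS_1026885,306-99-0,151707-03-8,1075687-38-5,862589-19-3,305849-27-8
7,97571-69-2,131662-80-1,306-95-6,25761-65-3,646533-88-2,23790-50-3,15038-90-1
8,33021-47-5,146304-71-4,NOCAS_1027599,61798-68-3,919293-77-9,548470-06-0,3824-74-6
9,306-99-0,126565-13-7,NOCAS_1026765,464-34-6,919293-78-0,NOCAS_1027003,61855-74-1
10,118945-64-5,446043-85-2,95827-25-1,NOCAS_1035154,55987-23-0,1127427-75-1,819792-77-3
11,307-07-3,NOCAS_1026915,118914-93-5,NOCAS_1026885,231953-37-0,146304-71-4,862130-87-8
12,105462-77-9,NOCAS_1026998,119141-86-5,55987-23-0,68541-01-5,649561-66-0,862130-95-8
13,125061-94-1,125061-94-1,114832-09-6,160248-96-4,151707-03-8,548434-15-7,862133-29-7
14,61855-74-1,87667-00-3,119141-87-6,NOCAS_1035147,675583-26-3,126565-13-7,151707-04-9
15,119107-96-9,61547-75-9,306-92-3,548455-52-3,667938-69-4,646533-88-2,61547-75-9
16,118945-65-6,NOCAS_1027048,662-28-2,916770-15-5,134880-89-0,231630-88-9,862130-67-4
17,95827-25-1,60131-74-0,60433-12-7,4314-47-0,61547-75-9,677033-16-8,NOCAS_1027003
18,NOCAS_1027599,662-28-2,306-94-5,1555-24-4,74582-85-7,61778-79-8,112242-89-4
19,444658-67-7,NOCAS_1026766,60433-11-6,548478-86-0,915-76-4,548478-86-0,24768-65-8
20,17051-14-8,876517-48-5,86714-34-3,305849-27-8,200862-70-0,1127427-64-8,146304-71-4
21,119141-86-5,919489-99-9,444658-67-7,57338-64-4,1555-24-4,61798-68-3,55987-23-0
22,306-95-6,116265-66-8,107349-88-2,NOCAS_1035142,234449-42-4,848352-66-9,862133-15-1
23,119107-97-0,48240-25-1,118945-64-5,NOCAS_1035206,864149-62-2,548455-85-2,NOCAS_1026997
24,114832-09-6,304658-31-9,49771-67-7,NOCAS_1035822,881689-01-6,NOCAS_1026885,306-99-0
25,68697-63-2,NOCAS_1009912,105462-77-9,240121-57-7,132877-69-1,749924-57-0,4314-47-0
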